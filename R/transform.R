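#' 12-parameter affine transform in world coordinates
#'
#' A 3x4 matrix `[A | t]` acting on world coordinates (mm): `y = A x + t`.
#' The pipeline's convention is that atlas-registration transforms map atlas
#' world coordinates into subject world coordinates; the direction is stored
#' with the object and serialized alongside the 12 numbers.
#'
#' @param matrix a 3x4 (or 4x4) matrix with invertible linear part.
#' @param direction free-text direction tag, default `"atlas_to_subject"`.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, direction = "atlas_to_subject") {
  matrix <- as.matrix(matrix)
  if (all(dim(matrix) == c(4L, 4L))) matrix <- matrix[1:3, , drop = FALSE]
  if (!all(dim(matrix) == c(3L, 4L)))
    stop("affine_transform requires a 3x4 (or 4x4) matrix")
  if (abs(det(matrix[, 1:3])) < 1e-12)
    stop("linear part of affine transform is not invertible")
  structure(list(matrix = matrix, direction = direction),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> direction:", x$direction, "\n")
  print(round(x$matrix, 5))
  invisible(x)
}

#' Identity affine transform
#' @param direction direction tag.
#' @export
affine_identity <- function(direction = "atlas_to_subject") {
  affine_transform(cbind(diag(3), 0), direction)
}

as_mat4 <- function(tr) rbind(tr$matrix, c(0, 0, 0, 1))

#' Build an affine transform from its 12 natural parameters
#'
#' The linear part is `Rz Ry Rx %*% Shear %*% diag(scale)`, applied about a
#' center point: `y = L (x - center) + center + translation`.
#'
#' @param translation length-3, mm.
#' @param rotation length-3 Euler angles in degrees (about x, y, z).
#' @param scale length-3 axis scale factors.
#' @param shear length-3 shear factors (xy, xz, yz).
#' @param center rotation/scale center in world mm.
#' @param direction direction tag.
#' @return an [affine_transform()].
#' @export
affine_from_params <- function(translation = c(0, 0, 0),
                               rotation = c(0, 0, 0),
                               scale = c(1, 1, 1),
                               shear = c(0, 0, 0),
                               center = c(0, 0, 0),
                               direction = "atlas_to_subject") {
  r <- rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, shear[1], shear[2]),
              c(0, 1, shear[3]),
              c(0, 0, 1))
  L <- Rz %*% Ry %*% Rx %*% Sh %*% diag(scale)
  t_full <- center + translation - L %*% center
  affine_transform(cbind(L, t_full), direction)
}

#' Compose and invert affine transforms
#'
#' `compose_affine(a, b)` returns the transform applying `b` first, then `a`.
#'
#' @param a,b,tr [affine_transform()] objects.
#' @return an [affine_transform()].
#' @export
compose_affine <- function(a, b) {
  m <- as_mat4(a) %*% as_mat4(b)
  affine_transform(m[1:3, , drop = FALSE], a$direction)
}

#' @rdname compose_affine
#' @export
invert_affine <- function(tr) {
  m <- solve(as_mat4(tr))
  dir <- tr$direction
  flipped <- switch(dir,
                    atlas_to_subject = "subject_to_atlas",
                    subject_to_atlas = "atlas_to_subject",
                    paste0("inverse_of:", dir))
  affine_transform(m[1:3, , drop = FALSE], flipped)
}

#' Apply an affine transform to world points
#' @param tr an [affine_transform()].
#' @param pts n x 3 matrix (or length-3 vector) of world coordinates.
#' @return n x 3 matrix of mapped coordinates.
#' @export
apply_affine <- function(tr, pts) {
  pts <- rbind(t(matrix(pts, ncol = 3)), 1)
  t((tr$matrix %*% pts))
}

#' Serialize an affine transform as a 12-number text file
#'
#' Format: comment header lines (`# direction: ...`), then the 3x4 matrix in
#' row-major order, one row per line.
#'
#' @param tr an [affine_transform()].
#' @param path output path.
#' @export
write_transform <- function(tr, path) {
  lines <- c(paste0("# memriz affine transform"),
             paste0("# direction: ", tr$direction),
             apply(tr$matrix, 1, function(r)
               paste(formatC(r, format = "g", digits = 17), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  dir_line <- grep("^# direction:", lines, value = TRUE)
  direction <- if (length(dir_line))
    sub("^# direction:\\s*", "", dir_line[1]) else "atlas_to_subject"
  num <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(num, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  affine_transform(m, direction)
}
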