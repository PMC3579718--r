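#' 3D scalar volume with voxel geometry
#'
#' The basic unit of the pipeline: a 3D intensity grid (arbitrary units)
#' together with its voxel spacing in mm and a 4x4 voxel-to-world affine.
#' World coordinates follow the RAS convention (x: left->right, y:
#' posterior->anterior, z: ventral->dorsal) with 0-based voxel indices mapping
#' to voxel centers.
#'
#' @param values 3D numeric array of intensities; must be finite.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param affine optional 4x4 voxel-to-world matrix. Default places the world
#'   origin at the grid center with axis-aligned voxel axes.
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(values, spacing, affine = NULL) {
  if (length(dim(values)) != 3L)
    stop("vol3d requires a 3D array, got ", length(dim(values)), " dimensions")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)")
  if (any(!is.finite(values)))
    stop("volume contains ", sum(!is.finite(values)), " non-finite voxels")
  if (is.null(affine)) {
    ctr <- (dim(values) - 1) / 2
    affine <- rbind(cbind(diag(spacing), -spacing * ctr), c(0, 0, 0, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine must be an invertible 4x4 voxel-to-world matrix")
  structure(list(values = values, spacing = as.numeric(spacing),
                 affine = affine, orientation = "RAS"),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vol3d> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.array.vol3d <- function(x, ...) x$values

#' @export
dim.vol3d <- function(x) dim(x$values)

#' Volume of one voxel in mm^3
#' @param x a `vol3d`, `label_vol` or `zscore_map`.
#' @return scalar mm^3.
#' @export
voxel_volume <- function(x) prod(x$spacing)

# Grid compatibility check used at every module boundary: shape and spacing
# must agree exactly; affines must agree to 1e-6 mm.
check_same_grid <- function(a, b, what = "volumes") {
  da <- if (is.array(a)) dim(a) else dim(a$values)
  db <- if (is.array(b)) dim(b) else dim(b$values)
  if (!identical(as.integer(da), as.integer(db)))
    stop("grid mismatch between ", what, ": shapes ",
         paste(da, collapse = "x"), " vs ", paste(db, collapse = "x"))
  if (!is.array(a) && !is.array(b)) {
    if (max(abs(a$spacing - b$spacing)) > 1e-9)
      stop("grid mismatch between ", what, ": spacings differ")
    if (max(abs(a$affine - b$affine)) > 1e-6)
      stop("grid mismatch between ", what, ": affines differ")
  }
  invisible(TRUE)
}

#' Labeled atlas volume
#'
#' An integer label grid sharing its geometry with a [vol3d()], plus an ROI
#' table mapping names to integer ids. Hippocampal subfields (CA1, DG) are
#' recorded with `parent = "hippocampus"` so that queries for the parent ROI
#' include its subfields.
#'
#' @param values 3D integer array of label ids (0 = background).
#' @param roi_table data.frame with columns `id`, `name` and optionally
#'   `parent` (NA for top-level ROIs). Must cover every nonzero id present.
#' @param spacing,affine grid geometry, as for [vol3d()].
#' @return An object of class `label_vol`.
#' @export
label_vol <- function(values, roi_table, spacing, affine = NULL) {
  if (length(dim(values)) != 3L) stop("label_vol requires a 3D array")
  storage.mode(values) <- "integer"
  if (any(values < 0L)) stop("label ids must be >= 0")
  if (is.null(roi_table$parent)) roi_table$parent <- NA_character_
  roi_table$id <- as.integer(roi_table$id)
  roi_table$name <- as.character(roi_table$name)
  present <- sort(unique(as.vector(values)))
  orphans <- setdiff(present[present != 0L], roi_table$id)
  if (length(orphans))
    stop("roi_table does not cover label ids present in the grid: ",
         paste(orphans, collapse = ", "))
  geom <- vol3d(array(0, dim(values)), spacing, affine)
  structure(list(values = values, roi_table = roi_table,
                 spacing = geom$spacing, affine = geom$affine),
            class = "label_vol")
}

#' @export
print.label_vol <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<label_vol> %d x %d x %d voxels, %d ROIs\n",
              d[1], d[2], d[3], sum(x$roi_table$id != 0L)))
  invisible(x)
}

#' @export
dim.label_vol <- function(x) dim(x$values)

#' Label ids belonging to an ROI, including its subfields
#'
#' @param labels a `label_vol`.
#' @param roi ROI name present in the label table.
#' @param include_children include ids whose `parent` is this ROI
#'   (e.g. CA1 and DG under hippocampus). Default TRUE.
#' @return integer vector of label ids.
#' @export
roi_ids <- function(labels, roi, include_children = TRUE) {
  tab <- labels$roi_table
  row <- tab[tab$name == roi, , drop = FALSE]
  if (nrow(row) == 0L) stop("ROI not present in label table: ", roi)
  ids <- row$id
  if (include_children)
    ids <- c(ids, tab$id[!is.na(tab$parent) & tab$parent == roi])
  unique(ids)
}

#' Logical mask of an ROI's voxels
#' @inheritParams roi_ids
#' @return logical 3D array.
#' @export
roi_mask <- function(labels, roi, include_children = TRUE) {
  array(labels$values %in% roi_ids(labels, roi, include_children),
        dim(labels$values))
}

#' Binary brain mask on a subject grid
#'
#' @param values logical (or coercible) 3D array; must contain at least one
#'   TRUE voxel.
#' @param spacing,affine grid geometry, as for [vol3d()].
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(values, spacing, affine = NULL) {
  if (length(dim(values)) != 3L) stop("brain_mask requires a 3D array")
  values <- array(as.logical(values), dim(values))
  if (!any(values)) stop("brain mask is empty")
  geom <- vol3d(array(0, dim(values)), spacing, affine)
  structure(list(values = values, spacing = geom$spacing,
                 affine = geom$affine),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s voxels, %d in mask (%.1f%%)\n",
              paste(dim(x$values), collapse = " x "), sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

# world <-> voxel maps (0-based voxel indices at voxel centers)
voxel_to_world <- function(affine, idx0) {
  idx0 <- rbind(t(idx0), 1)
  t((affine %*% idx0)[1:3, , drop = FALSE])
}

world_to_voxel <- function(affine, xyz) {
  xyz <- rbind(t(xyz), 1)
  t((solve(affine) %*% xyz)[1:3, , drop = FALSE])
}
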