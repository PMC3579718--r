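#' Zero non-brain voxels
#'
#' Voxels outside the mask are set exactly to 0; in-mask voxels are
#' unchanged.
#'
#' @param image a [vol3d()].
#' @param mask a [brain_mask()] on the same grid.
#' @return a [vol3d()].
#' @export
apply_brain_mask <- function(image, mask) {
  check_same_grid(image, mask, "image and mask")
  if (!any(mask$values)) stop("brain mask is empty")
  out <- image
  out$values[!mask$values] <- 0
  out
}

#' Denoise a volume without altering its resolution
#'
#' Two non-linear filters are available: a 3D median filter (default,
#' radius-1 cubic window) and Perona–Malik anisotropic diffusion. The output
#' grid is identical to the input; if a mask is supplied, voxels outside it
#' remain exactly 0.
#'
#' @param image a [vol3d()].
#' @param method `"median3d"` or `"aniso_diffusion"`.
#' @param radius median window radius in voxels (>= 1).
#' @param iterations,kappa,lambda diffusion parameters: iteration count,
#'   edge-stopping scale (intensity units; default 10% of the intensity
#'   range) and step size in (0, 1/6].
#' @param mask optional [brain_mask()]; its complement is re-zeroed after
#'   filtering.
#' @return a [vol3d()] on the same grid.
#' @export
denoise <- function(image, method = c("median3d", "aniso_diffusion"),
                    radius = 1L, iterations = 5L, kappa = NULL,
                    lambda = 1 / 6, mask = NULL) {
  method <- match.arg(method)
  dims <- dim(image$values)
  if (method == "median3d") {
    if (radius < 1) stop("median radius must be a positive integer")
    vals <- cpp_median3d(as.vector(image$values), dims, as.integer(radius))
  } else {
    rng <- diff(range(image$values))
    if (is.null(kappa)) kappa <- if (rng > 0) 0.1 * rng else 1
    if (lambda <= 0 || lambda > 1 / 6)
      stop("diffusion step lambda must be in (0, 1/6]")
    x <- image$values
    shift <- function(a, ax, by) {
      idx <- rep(list(quote(expr = )), 3)
      n <- dims[ax]
      src <- pmin(pmax(seq_len(n) + by, 1L), n)
      idx[[ax]] <- src
      do.call(`[`, c(list(a), idx))
    }
    for (it in seq_len(iterations)) {
      acc <- array(0, dims)
      for (ax in 1:3) for (by in c(-1L, 1L)) {
        g <- shift(x, ax, by) - x
        acc <- acc + exp(-(g / kappa)^2) * g
      }
      x <- x + lambda * acc
    }
    vals <- x
  }
  out <- image
  out$values <- array(vals, dims)
  if (!is.null(mask)) {
    check_same_grid(image, mask, "image and mask")
    out$values[!mask$values] <- 0
  }
  out
}

#' Fallback brain-mask generator for phantoms
#'
#' Otsu threshold, largest 6-connected foreground component, then a
#' morphological closing. Intended for simulated data; real rodent scans are
#' expected to arrive with externally produced masks.
#'
#' @param image a [vol3d()].
#' @param nbins histogram bins for the Otsu threshold.
#' @param closing_iter closing iterations (dilate then erode).
#' @return a [brain_mask()].
#' @export
auto_brain_mask <- function(image, nbins = 256L, closing_iter = 1L) {
  v <- as.vector(image$values)
  thr <- otsu_threshold(v, nbins)
  fg <- v > thr
  if (!any(fg)) stop("Otsu threshold removed every voxel")
  dims <- dim(image$values)
  comp <- cpp_label_components(fg, dims)
  keep <- which.max(tabulate(comp[comp > 0L]))
  m <- comp == keep
  for (i in seq_len(closing_iter)) m <- cpp_morph3d(m, dims, TRUE)
  for (i in seq_len(closing_iter)) m <- cpp_morph3d(m, dims, FALSE)
  brain_mask(array(m, dims), image$spacing, image$affine)
}

otsu_threshold <- function(v, nbins = 256L) {
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(findInterval(v, seq(r[1], r[2], length.out = nbins + 1L),
                             all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- seq(r[1], r[2], length.out = nbins + 1L)[-1] - diff(r) / (2 * nbins)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Resample a volume through an affine transform onto a target grid
#'
#' `transform` maps the moving image's world coordinates into the target's
#' world coordinates (the pipeline's atlas-to-subject direction). Each target
#' voxel center is pulled back through the inverse transform and the moving
#' image is interpolated there; out-of-field voxels receive `fill`.
#'
#' @param image moving [vol3d()].
#' @param transform an [affine_transform()].
#' @param target [vol3d()] (or any object with `spacing`/`affine`/grid)
#'   defining the output grid.
#' @param interp `"trilinear"` or `"nearest"`.
#' @param fill out-of-field value.
#' @return a [vol3d()] on the target grid.
#' @export
resample_volume <- function(image, transform, target,
                            interp = c("trilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  # source index = inv(A_src) %*% inv(T) %*% A_tgt %*% target index
  full <- solve(image$affine) %*% solve(as_mat4(transform)) %*% target$affine
  vals <- cpp_resample3d(as.vector(image$values), dim(image$values),
                         dim(target$values), as.vector(full[1:3, ]),
                         if (interp == "nearest") 0L else 1L, fill)
  vol3d(array(vals, dim(target$values)), target$spacing, target$affine)
}

#' Propagate atlas labels into subject space
#'
#' Nearest-neighbour interpolation only, so label identities are preserved
#' and no new ids can appear; out-of-field voxels become 0.
#'
#' @param labels a [label_vol()] (atlas space).
#' @param transform an [affine_transform()] mapping atlas world to the
#'   target's world.
#' @param target a [vol3d()] defining the subject grid.
#' @return a [label_vol()] on the target grid.
#' @export
warp_labels <- function(labels, transform, target) {
  full <- solve(labels$affine) %*% solve(as_mat4(transform)) %*% target$affine
  vals <- cpp_resample3d(as.numeric(labels$values), dim(labels$values),
                         dim(target$values), as.vector(full[1:3, ]), 0L, 0)
  label_vol(array(as.integer(vals), dim(target$values)), labels$roi_table,
            target$spacing, target$affine)
}

#' Apply scripted label edits
#'
#' Scripted replacement for interactive correction of propagated labels:
#' each edit reassigns one voxel to a new id. Later edits win on overlap;
#' the full edit log is retained on the result for provenance.
#'
#' @param labels a [label_vol()].
#' @param edits data.frame with columns `i,j,k` (1-based voxel indices) and
#'   `new_id`; ids must exist in the ROI table.
#' @return a [label_vol()] with attribute `edit_log`.
#' @export
adjust_labels <- function(labels, edits) {
  out <- labels
  prior <- attr(labels, "edit_log")
  if (is.null(edits) || nrow(edits) == 0L) {
    attr(out, "edit_log") <- prior
    return(out)
  }
  if (!all(c("i", "j", "k", "new_id") %in% names(edits)))
    stop("edits must have columns i,j,k,new_id")
  bad <- setdiff(unique(edits$new_id), labels$roi_table$id)
  if (length(bad))
    stop("edit would create id(s) absent from roi_table: ",
         paste(bad, collapse = ", "))
  dims <- dim(labels$values)
  if (any(edits$i < 1 | edits$i > dims[1] | edits$j < 1 | edits$j > dims[2] |
          edits$k < 1 | edits$k > dims[3]))
    stop("edit voxel indices out of range")
  lin <- cbind(edits$i, edits$j, edits$k)
  for (r in seq_len(nrow(edits)))       # row order = application order
    out$values[lin[r, 1], lin[r, 2], lin[r, 3]] <- as.integer(edits$new_id[r])
  attr(out, "edit_log") <- rbind(prior, edits)
  out
}
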