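#' Voxel-wise Z-score normalization over the brain mask
#'
#' Each in-mask voxel intensity x_i is mapped to Z_i = (x_i - xbar) / sigma,
#' where xbar and sigma are the mean and population (1/N) standard deviation
#' of intensity over the in-mask voxels only. This removes between-scan
#' global intensity variability so that a fixed threshold (Z >= 1, i.e. one
#' standard deviation above the whole-brain mean) samples comparably
#' enhanced voxels in every subject. Out-of-mask voxels are set to 0 and
#' excluded from all downstream statistics.
#'
#' @param image a [vol3d()].
#' @param mask a [brain_mask()] on the same grid with >= 2 voxels.
#' @return An object of class `zscore_map`: values, mask, provenance
#'   `brain_mean` and `brain_sd`, and `threshold` (NULL until
#'   [threshold_map()] is applied).
#' @export
zscore_normalize <- function(image, mask) {
  check_same_grid(image, mask, "image and mask")
  x <- image$values[mask$values]
  if (length(x) < 2L) stop("mask must contain at least 2 voxels")
  xbar <- mean(x)
  sigma <- sqrt(mean((x - xbar)^2))     # population SD over the brain
  if (sigma == 0)
    stop("cannot z-normalize: zero intensity variance over the brain mask")
  vals <- array(0, dim(image$values))
  vals[mask$values] <- (x - xbar) / sigma
  structure(list(values = vals, mask = mask, spacing = image$spacing,
                 affine = image$affine, brain_mean = xbar, brain_sd = sigma,
                 threshold = NULL),
            class = "zscore_map")
}

#' @export
print.zscore_map <- function(x, ...) {
  cat(sprintf("<zscore_map> %s voxels, %d in mask\n",
              paste(dim(x$values), collapse = " x "), sum(x$mask$values)))
  cat(sprintf("  brain mean %.6g, brain sd %.6g, threshold %s\n",
              x$brain_mean, x$brain_sd,
              if (is.null(x$threshold)) "none" else
                format(x$threshold)))
  invisible(x)
}

#' @export
dim.zscore_map <- function(x) dim(x$values)

#' Threshold a Z-score map
#'
#' In-mask voxels below the pre-set threshold (default Z_t = 1) are set to
#' zero; voxels at or above it are unchanged. The threshold is recorded on
#' the result; thresholding an already-thresholded map is an explicit error
#' rather than a silent idempotent pass, and the un-thresholded map should
#' be retained for histogram and fraction censuses.
#'
#' @param zmap a [zscore_normalize()] result with no threshold applied.
#' @param z_t threshold in Z units (default 1).
#' @return a `zscore_map` with `threshold = z_t`.
#' @export
threshold_map <- function(zmap, z_t = 1) {
  stopifnot(inherits(zmap, "zscore_map"))
  if (!is.null(zmap$threshold))
    stop("map already thresholded at Z >= ", zmap$threshold,
         "; threshold the un-thresholded map instead")
  out <- zmap
  below <- zmap$mask$values & (zmap$values < z_t)
  out$values[below] <- 0
  out$threshold <- z_t
  out
}

#' Fraction of in-mask voxels at or above a threshold
#'
#' Computed on the un-thresholded map; monotone non-increasing in `z_t`.
#'
#' @param zmap un-thresholded `zscore_map`.
#' @param z_t threshold in Z units.
#' @return fraction in \[0, 1\].
#' @export
suprathreshold_fraction <- function(zmap, z_t = 1) {
  stopifnot(inherits(zmap, "zscore_map"))
  if (!is.null(zmap$threshold))
    stop("suprathreshold_fraction requires the un-thresholded map")
  if (!any(zmap$mask$values)) stop("brain mask is empty")
  mean(zmap$values[zmap$mask$values] >= z_t)
}

#' Per-group intensity histogram census of Z-score maps
#'
#' Counts in-mask voxels per Z bin for each subject and summarizes each
#' group as mean count +/- standard error per bin. Values outside the edge
#' range are clamped into the extreme bins so that every subject's counts
#' sum to its mask size.
#'
#' @param zmaps list of un-thresholded `zscore_map`s.
#' @param groups character vector of group labels, one per map.
#' @param subjects optional subject ids (default S1, S2, ...).
#' @param bin_edges shared bin edges in Z units; default width 0.25 over
#'   \[-5, 8\].
#' @return An object of class `histogram_census`: `counts` (long data.frame
#'   bin_lo,bin_hi,subject,group,count) and `summary` (bin_lo,bin_hi,group,
#'   mean_count,se_count).
#' @export
histogram_census <- function(zmaps, groups,
                             subjects = sprintf("S%d", seq_along(zmaps)),
                             bin_edges = seq(-5, 8, by = 0.25)) {
  stopifnot(length(zmaps) >= 1L, length(groups) == length(zmaps),
            length(subjects) == length(zmaps))
  nb <- length(bin_edges) - 1L
  counts <- vector("list", length(zmaps))
  for (i in seq_along(zmaps)) {
    zm <- zmaps[[i]]
    stopifnot(inherits(zm, "zscore_map"))
    check_same_grid(zm$values, zm$mask$values, "z-map and mask")
    z <- zm$values[zm$mask$values]
    bin <- findInterval(z, bin_edges, all.inside = TRUE)  # clamps extremes
    counts[[i]] <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                              bin_hi = bin_edges[-1],
                              subject = subjects[i], group = groups[i],
                              count = tabulate(bin, nb),
                              stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, counts)
  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  agg_m <- stats::aggregate(count ~ bin_lo + bin_hi + group, long, mean)
  agg_s <- stats::aggregate(count ~ bin_lo + bin_hi + group, long, se)
  names(agg_m)[4] <- "mean_count"
  agg_m$se_count <- agg_s$count
  structure(list(counts = long, summary = agg_m, bin_edges = bin_edges),
            class = "histogram_census")
}

#' @export
print.histogram_census <- function(x, ...) {
  cat(sprintf("<histogram_census> %d bins, %d subjects, groups: %s\n",
              length(x$bin_edges) - 1L, length(unique(x$counts$subject)),
              paste(unique(x$counts$group), collapse = ", ")))
  invisible(x)
}

#' Write a Z-score map as NIfTI-1 float32
#' @param zmap a `zscore_map`.
#' @param path output path.
#' @export
write_zmap <- function(zmap, path) {
  write_volume(vol3d(zmap$values, zmap$spacing, zmap$affine), path)
}
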