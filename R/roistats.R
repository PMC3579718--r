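#' Per-ROI suprathreshold metrics from a thresholded Z-score map
#'
#' For one ROI: total voxel count and volume, suprathreshold voxel count
#' (Z >= Z_t), mean Z over suprathreshold voxels only ("mean signal"), and
#' active volume in mm^3 ("activated volume"). An ROI with no suprathreshold
#' voxels legitimately has active volume 0 and `mean_supra_z = NA` (recording
#' 0 would bias group means toward the threshold); NA entries are dropped
#' pairwise by the group tests.
#'
#' @param zmap a thresholded `zscore_map` (see [threshold_map()]).
#' @param labels a [label_vol()] on the same grid.
#' @param roi ROI name (subfields included via the ROI table's parent links).
#' @param subject_id,group optional identifiers copied into the record.
#' @return one-row data.frame (an ROIRecord): subject_id, group, roi,
#'   n_voxels_total, n_voxels_suprathreshold, mean_supra_z,
#'   active_volume_mm3, roi_volume_mm3, z_threshold.
#' @export
roi_metrics <- function(zmap, labels, roi, subject_id = NA_character_,
                        group = NA_character_) {
  stopifnot(inherits(zmap, "zscore_map"))
  if (is.null(zmap$threshold))
    stop("roi_metrics requires a thresholded z-map; call threshold_map() first")
  check_same_grid(zmap$values, labels$values, "z-map and labels")
  sel <- roi_mask(labels, roi) & zmap$mask$values
  z <- zmap$values[sel]
  supra <- z >= zmap$threshold
  vv <- prod(zmap$spacing)
  data.frame(subject_id = subject_id, group = group, roi = roi,
             n_voxels_total = length(z),
             n_voxels_suprathreshold = sum(supra),
             mean_supra_z = if (any(supra)) mean(z[supra]) else NA_real_,
             active_volume_mm3 = sum(supra) * vv,
             roi_volume_mm3 = length(z) * vv,
             z_threshold = zmap$threshold,
             stringsAsFactors = FALSE)
}

#' All-ROI metrics table for one subject
#'
#' @inheritParams roi_metrics
#' @param rois ROI names; default every top-level ROI except background.
#' @return data.frame, one ROIRecord row per ROI.
#' @export
roi_metrics_all <- function(zmap, labels, rois = NULL,
                            subject_id = NA_character_,
                            group = NA_character_) {
  if (is.null(rois)) {
    tab <- labels$roi_table
    rois <- tab$name[tab$id != 0L & is.na(tab$parent)]
  }
  do.call(rbind, lapply(rois, function(r)
    roi_metrics(zmap, labels, r, subject_id, group)))
}

#' Relative intensity of an ROI, normalized by whole-brain mean
#'
#' Mean raw intensity over the ROI divided by the mean over the in-mask
#' brain; invariant to global positive rescaling of the image.
#'
#' @param image a [vol3d()] (raw or denoised intensities).
#' @param labels a [label_vol()] on the same grid.
#' @param roi ROI name.
#' @param mask a [brain_mask()].
#' @return dimensionless scalar.
#' @export
relative_intensity <- function(image, labels, roi, mask) {
  check_same_grid(image, labels$values, "image and labels")
  check_same_grid(image, mask, "image and mask")
  sel <- roi_mask(labels, roi)
  if (!any(sel)) stop("ROI is empty: ", roi)
  brain_mean <- mean(image$values[mask$values])
  if (!is.finite(brain_mean) || brain_mean == 0)
    stop("whole-brain mean is zero; cannot normalize")
  mean(image$values[sel]) / brain_mean
}

#' CA1:DG intensity ratio
#'
#' Ratio of the two subfields' relative intensities; the whole-brain
#' normalizer cancels, so this equals the plain CA1-mean / DG-mean ratio.
#'
#' @inheritParams relative_intensity
#' @return dimensionless scalar.
#' @export
ca1_dg_ratio <- function(image, labels, mask) {
  relative_intensity(image, labels, "CA1", mask) /
    relative_intensity(image, labels, "DG", mask)
}

#' Dorsoventral hippocampal thickness at a stereotaxic position
#'
#' On the coronal slice nearest `ap_coordinate` (world mm, bregma-anchored),
#' in the voxel column `lateral_offset` mm from the midsagittal plane on
#' each hemisphere, thickness is the length of the contiguous run of
#' hippocampus-labeled voxels (subfields included) containing the dorsal-most
#' hippocampal voxel, times the dorsoventral spacing. Both hemispheres are
#' measured and averaged; a column that misses the hippocampus entirely is
#' flagged as missing (NA), not zero.
#'
#' @param labels a [label_vol()] with bregma-anchored affine.
#' @param ap_coordinate anterior-posterior position in world mm
#'   (default -2, i.e. Bregma -2 mm).
#' @param lateral_offset lateral distance from the midline in mm
#'   (default 1.5).
#' @return one-row data.frame: thickness_mm (mean of available sides),
#'   thickness_left_mm, thickness_right_mm.
#' @export
hippocampal_thickness <- function(labels, ap_coordinate = -2,
                                  lateral_offset = 1.5) {
  ids <- roi_ids(labels, "hippocampus")
  dims <- dim(labels$values)
  inv <- solve(rbind(labels$affine))
  vox_at <- function(world) (inv %*% c(world, 1))[1:3] # 0-based continuous
  one_side <- function(sign) {
    v <- vox_at(c(sign * lateral_offset, ap_coordinate, 0))
    i <- round(v[1]) + 1L
    j <- round(v[2]) + 1L
    if (i < 1L || i > dims[1] || j < 1L || j > dims[2]) return(NA_real_)
    col <- labels$values[i, j, ] %in% ids
    if (!any(col)) return(NA_real_)
    runs <- rle(col)
    ends <- cumsum(runs$lengths)
    hip_runs <- which(runs$values)
    dorsal <- hip_runs[which.max(ends[hip_runs])]   # run containing topmost
    runs$lengths[dorsal] * labels$spacing[3]
  }
  left <- one_side(-1)
  right <- one_side(+1)
  vals <- c(left, right)
  data.frame(thickness_mm = if (all(is.na(vals))) NA_real_
             else mean(vals, na.rm = TRUE),
             thickness_left_mm = left, thickness_right_mm = right)
}

#' Segmented ROI volume in mm^3
#'
#' @param labels a [label_vol()].
#' @param roi ROI name (subfields included for parents).
#' @return scalar mm^3 (voxel count times voxel volume).
#' @export
segmented_volume <- function(labels, roi) {
  n <- sum(roi_mask(labels, roi))
  if (n == 0L) stop("ROI is empty: ", roi)
  n * prod(labels$spacing)
}

#' Group volume ratio as a percentage
#'
#' `100 * mean(volumes_mutant) / mean(volumes_control)`; e.g. a cohort with
#' 30% hippocampal volume loss yields about 70.
#'
#' @param volumes_mutant,volumes_control numeric vectors of per-subject
#'   volumes (mm^3).
#' @return percent.
#' @export
group_volume_ratio <- function(volumes_mutant, volumes_control) {
  if (!length(volumes_mutant) || !length(volumes_control))
    stop("both groups must be nonempty")
  100 * mean(volumes_mutant) / mean(volumes_control)
}

#' Hippocampal sub-region metrics for one subject
#'
#' The Fig-4-style readouts on the relative-intensity scale (not the
#' thresholded Z scale): CA1 and DG relative intensity, their ratio,
#' hippocampal thickness, and segmented volumes of the whole hippocampus and
#' its dorsal CA1 / DG subfields.
#'
#' @inheritParams relative_intensity
#' @param ap_coordinate,lateral_offset see [hippocampal_thickness()].
#' @param subject_id,group optional identifiers.
#' @return one-row data.frame (a SubregionRecord).
#' @export
subregion_metrics <- function(image, labels, mask, ap_coordinate = -2,
                              lateral_offset = 1.5,
                              subject_id = NA_character_,
                              group = NA_character_) {
  ca1 <- relative_intensity(image, labels, "CA1", mask)
  dg <- relative_intensity(image, labels, "DG", mask)
  th <- hippocampal_thickness(labels, ap_coordinate, lateral_offset)
  data.frame(subject_id = subject_id, group = group,
             rel_intensity_CA1 = ca1, rel_intensity_DG = dg,
             ca1_dg_ratio = ca1 / dg,
             hippocampal_thickness_mm = th$thickness_mm,
             hippocampus_volume_mm3 = segmented_volume(labels, "hippocampus"),
             ca1_volume_mm3 = segmented_volume(labels, "CA1"),
             dg_volume_mm3 = segmented_volume(labels, "DG"),
             stringsAsFactors = FALSE)
}
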