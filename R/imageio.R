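#' Read a 3D volume from NIfTI-1
#'
#' Geometry (spacing, affine) is taken from the header; no resampling is
#' performed. Inputs are reoriented to the canonical RAS convention on load.
#' 4D series and volumes containing non-finite voxels are rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [vol3d()].
#' @export
read_volume <- function(path) {
  nii <- read_nifti_ras(path)
  vals <- as.array(nii)
  if (length(dim(vals)) == 4L && dim(vals)[4] == 1L)
    vals <- array(as.vector(vals), dim(vals)[1:3])
  if (length(dim(vals)) != 3L)
    stop("expected a 3D volume, got ", length(dim(vals)),
         " dimensions in ", path)
  vals <- array(as.vector(vals), dim(vals))   # strip header attributes
  nbad <- sum(!is.finite(vals))
  if (nbad > 0)
    stop("volume contains ", nbad, " non-finite voxels: ", path)
  aff <- structure(RNifti::xform(nii), code = NULL)
  vol3d(vals, spacing = sqrt(colSums(aff[1:3, 1:3]^2)), affine = aff)
}

read_nifti_ras <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nii <- RNifti::readNifti(path)
  ori <- try(RNifti::orientation(nii), silent = TRUE)
  if (!inherits(ori, "try-error") && !identical(ori, "RAS"))
    RNifti::orientation(nii) <- "RAS"
  nii
}

#' Write a volume (or mask) as NIfTI-1
#'
#' Intensities are stored as float32 (lossless for float32-representable
#' values); masks as uint8.
#'
#' @param image a [vol3d()] or [brain_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  is_mask <- inherits(image, "brain_mask")
  vals <- if (is_mask) array(as.integer(image$values), dim(image$values))
          else image$values
  nii <- make_nifti(vals, image, if (is_mask) "uint8" else "float")
  RNifti::writeNifti(nii, path)
  invisible(path)
}

# geometry must be attached before asNifti (pixdim attribute), then both
# transform slots set so any reader reconstructs the same world mapping
make_nifti <- function(vals, image, datatype) {
  nii <- RNifti::asNifti(structure(vals, pixdim = image$spacing),
                         datatype = datatype)
  xf <- structure(image$affine, code = 2L)
  nii <- RNifti::`sform<-`(nii, xf)
  RNifti::`qform<-`(nii, xf)
}

#' Read a brain mask from NIfTI-1
#' @param path NIfTI file with 0/1 voxels.
#' @return a [brain_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  brain_mask(v$values != 0, v$spacing, v$affine)
}

#' Read a label volume and its ROI table
#'
#' @param path NIfTI file with integer labels.
#' @param roi_table_path two/three-column CSV (`id,name[,parent]`). Every
#'   nonzero id present in the grid must appear in the table.
#' @return a [label_vol()].
#' @export
read_labels <- function(path, roi_table_path) {
  nii <- read_nifti_ras(path)
  vals <- as.array(nii)
  if (length(dim(vals)) != 3L)
    stop("expected a 3D label volume, got ", length(dim(vals)),
         " dimensions in ", path)
  if (any(!is.finite(vals)) || any(vals != round(vals)))
    stop("label volume contains non-integer voxels: ", path)
  tab <- read_roi_table(roi_table_path)
  aff <- structure(RNifti::xform(nii), code = NULL)
  label_vol(array(as.integer(vals), dim(vals)), tab,
            spacing = sqrt(colSums(aff[1:3, 1:3]^2)), affine = aff)
}

#' Write a label volume as NIfTI-1 (int16) plus its ROI table CSV
#' @param labels a [label_vol()].
#' @param path output NIfTI path.
#' @param roi_table_path optional CSV path for the ROI table.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, roi_table_path = NULL) {
  nii <- make_nifti(labels$values, labels, "int16")
  RNifti::writeNifti(nii, path)
  if (!is.null(roi_table_path)) write_roi_table(labels$roi_table, roi_table_path)
  invisible(path)
}

#' @rdname read_labels
#' @export
read_roi_table <- function(roi_table_path) {
  if (!file.exists(roi_table_path))
    stop("file not found: ", roi_table_path)
  tab <- utils::read.csv(roi_table_path, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(tab)))
    stop("ROI table must have columns id,name")
  if (is.null(tab$parent)) tab$parent <- NA_character_
  tab$parent[tab$parent %in% c("", "NA")] <- NA_character_
  tab
}

write_roi_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write tabular records as CSV
#'
#' An empty record list yields a header-only CSV when column names are
#' supplied via an empty data.frame.
#'
#' @param records a data.frame (possibly 0-row).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  ok <- try(utils::write.csv(records, path, row.names = FALSE, na = ""),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write table to ", path)
  invisible(path)
}

#' Read / write a cohort manifest
#'
#' A manifest lists one subject per row: `subject_id,group,volume_path,
#' mask_path` (optionally `labels_path` for phantom ground truth). Paths are
#' checked for existence on read.
#'
#' @param path CSV path.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "volume_path", "mask_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ","))
  if (anyDuplicated(man$subject_id))
    stop("duplicate subject ids in manifest")
  pcols <- intersect(c("volume_path", "mask_path", "labels_path"), names(man))
  for (pc in pcols) {
    missing <- man[[pc]][!file.exists(man[[pc]])]
    if (length(missing))
      stop("manifest paths not resolvable: ", paste(missing, collapse = ", "))
  }
  man
}
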