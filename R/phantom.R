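# Digital mouse-brain phantom: nested ellipsoid/shell geometry with the 12
# standard atlas ROIs, hippocampal CA1/DG subfields arranged as a dorsal slab
# (CA1 sheet on top, DG below) so a dorsoventral thickness is measurable, and
# interior ventricles. Geometry is deterministic given (shape, spacing, seed);
# the seed only jitters ROI centers/sizes by a few percent.

phantom_roi_table <- function() {
  data.frame(
    id = 0:15,
    name = c("background", "neocortex", "olfactory_bulb", "cerebellum",
             "brainstem", "midbrain", "thalamus", "hypothalamus",
             "striatum", "globus_pallidus", "septum_basal_forebrain",
             "amygdala", "hippocampus", "CA1", "DG", "ventricles"),
    parent = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
               "hippocampus", "hippocampus", NA),
    stringsAsFactors = FALSE)
}

# Baseline tissue intensity per label (arbitrary units): distinct regional
# T1-weighted contrast as in a real template (white-matter-rich structures
# darker, cell-dense layers brighter), ventricles dark as CSF is on T1.
# The contrast spread also makes atlas-to-subject registration well-posed.
phantom_base_intensity <- function() {
  c(background = 0, neocortex = 1.10, olfactory_bulb = 1.05,
    cerebellum = 1.15, brainstem = 0.90, midbrain = 1.00, thalamus = 1.12,
    hypothalamus = 0.95, striatum = 1.08, globus_pallidus = 0.85,
    septum_basal_forebrain = 0.98, amygdala = 1.03, hippocampus = 1.12,
    CA1 = 1.19, DG = 1.19, ventricles = 0.3)
}

#' Build a labeled digital mouse-brain phantom
#'
#' Constructs a deterministic nested-ellipsoid brain with the 12 standard
#' atlas ROIs (neocortex, striatum, globus pallidus, olfactory bulb,
#' hypothalamus, septum/basal forebrain, midbrain, brainstem, thalamus,
#' hippocampus, amygdala, cerebellum), hippocampal CA1 and DG subfields
#' forming a dorsal slab of known thickness, and interior ventricles. The
#' affine anchors a nominal bregma at world origin with the hippocampal slab
#' centered at AP = -2 mm, so stereotaxic coronal coordinates are
#' well-defined.
#'
#' @param grid_shape integer length-3 (or scalar, cubed); each axis >= 32.
#' @param voxel_spacing mm per axis (scalar or length-3). Default
#'   `c(0.2, 0.156, 0.3)`, echoing a typical T1-weighted mouse acquisition.
#' @param geometry_seed integer; jitters ROI centers/sizes by up to ~2%.
#' @return An object of class `atlas_phantom`: list with `template`
#'   ([vol3d()]), `labels` ([label_vol()]), `roi_table`, `voxel_spacing`,
#'   and `slab_thickness_mm` (ground-truth hippocampal slab thickness).
#' @export
build_atlas_phantom <- function(grid_shape = c(128L, 128L, 64L),
                                voxel_spacing = c(0.2, 0.156, 0.3),
                                geometry_seed = 1L) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 32L))
    stop("grid too small to place all ROIs: need >= 32 voxels per axis")
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  if (any(voxel_spacing <= 0)) stop("voxel spacing must be > 0")

  set.seed(as.integer(geometry_seed))
  jit <- function(n = 3L) runif(n, -0.02, 0.02)

  fov <- grid_shape * voxel_spacing
  semi <- 0.42 * fov                      # brain semi-axes, mm
  ctr_idx <- (grid_shape - 1) / 2
  # bregma at world origin; brain center (= hippocampal AP center) at y = -2
  brain_ctr <- c(0, -2, 0)
  origin <- brain_ctr - voxel_spacing * ctr_idx
  affine <- rbind(cbind(diag(voxel_spacing), origin), c(0, 0, 0, 1))

  # world coordinate grids, centered on the brain, in units of the semi-axes
  gx <- (0:(grid_shape[1] - 1)) * voxel_spacing[1] + origin[1] - brain_ctr[1]
  gy <- (0:(grid_shape[2] - 1)) * voxel_spacing[2] + origin[2] - brain_ctr[2]
  gz <- (0:(grid_shape[3] - 1)) * voxel_spacing[3] + origin[3] - brain_ctr[3]
  X <- array(rep(gx, times = prod(grid_shape[2:3])), grid_shape) / semi[1]
  Y <- array(rep(rep(gy, each = grid_shape[1]), times = grid_shape[3]),
             grid_shape) / semi[2]
  Z <- array(rep(gz, each = prod(grid_shape[1:2])), grid_shape) / semi[3]

  ell <- function(cx, cy, cz, sx, sy, sz)
    ((X - cx) / sx)^2 + ((Y - cy) / sy)^2 + ((Z - cz) / sz)^2 <= 1

  lab <- array(0L, grid_shape)
  brain <- ell(0, 0, 0, 1, 1, 1)

  paint <- list()
  # dorsal cortical shell
  paint$neocortex <- brain & !ell(0, 0, 0, 0.78, 0.78, 0.78) &
    Z > 0 & Y > -0.75 & Y < 0.85
  j <- jit(); paint$olfactory_bulb <- ell(0 + j[1], 0.74 + j[2], 0.05 + j[3],
                                          0.30, 0.22, 0.30)
  j <- jit(); paint$cerebellum <- ell(0 + j[1], -0.70 + j[2], 0.22 + j[3],
                                      0.42, 0.24, 0.32)
  j <- jit(); paint$brainstem <- ell(0 + j[1], -0.68 + j[2], -0.30 + j[3],
                                     0.34, 0.28, 0.30)
  j <- jit(); paint$midbrain <- ell(0 + j[1], -0.38 + j[2], 0 + j[3],
                                    0.30, 0.18, 0.26)
  j <- jit(); paint$thalamus <- ell(0 + j[1], -0.05 + j[2], -0.10 + j[3],
                                    0.28, 0.18, 0.20)
  j <- jit(); paint$hypothalamus <- ell(0 + j[1], 0.05 + j[2], -0.42 + j[3],
                                        0.26, 0.18, 0.18)
  j <- jit(); paint$striatum <- ell(0.38 + j[1], 0.38 + j[2], -0.05 + j[3],
                                    0.20, 0.20, 0.24) |
    ell(-0.38 - j[1], 0.38 + j[2], -0.05 + j[3], 0.20, 0.20, 0.24)
  j <- jit(); paint$globus_pallidus <- ell(0.30 + j[1], 0.30 + j[2],
                                           -0.20 + j[3], 0.11, 0.11, 0.13) |
    ell(-0.30 - j[1], 0.30 + j[2], -0.20 + j[3], 0.11, 0.11, 0.13)
  j <- jit(); paint$septum_basal_forebrain <-
    ell(0 + j[1], 0.42 + j[2], -0.28 + j[3], 0.15, 0.18, 0.20)
  j <- jit(); paint$amygdala <- ell(0.52 + j[1], 0.12 + j[2], -0.35 + j[3],
                                    0.14, 0.14, 0.14) |
    ell(-0.52 - j[1], 0.12 + j[2], -0.35 + j[3], 0.14, 0.14, 0.14)

  # hippocampal slab: dorsal sheet spanning laterally, thickness known;
  # sized (with amygdala) to a realistic few percent of brain volume. The
  # slab is built from whole z-layers (at least 3, so CA1 and DG sheets
  # exist at the smallest grids): CA1 is the dorsal third of layers, DG the
  # ventral third.
  z0 <- 0.28
  th <- 0.20
  zlay <- which(gz / semi[3] >= z0 & gz / semi[3] < z0 + th)
  if (length(zlay) < 3L) {
    start <- which(gz / semi[3] >= z0)[1]
    if (is.na(start) || start + 2L > grid_shape[3])
      stop("grid too small to place all ROIs: cannot place hippocampus")
    zlay <- start:(start + 2L)
  }
  K <- array(rep(seq_len(grid_shape[3]), each = prod(grid_shape[1:2])),
             grid_shape)
  nl <- length(zlay)
  k_dg <- zlay[seq_len(max(1L, floor(nl / 3)))]
  k_ca1 <- zlay[(nl - max(1L, floor(nl / 3)) + 1L):nl]
  slab <- abs(X) <= 0.55 & Y >= -0.22 & Y <= 0.22 &
    K %in% zlay & ell(0, 0, 0, 0.92, 0.92, 0.92)
  paint$hippocampus <- slab
  paint$CA1 <- slab & K %in% k_ca1                  # dorsal CA1 sheet
  paint$DG <- slab & K %in% k_dg                    # ventral DG sheet
  j <- jit(); paint$ventricles <- ell(0.15 + j[1], 0 + j[2], 0.10 + j[3],
                                      0.06, 0.25, 0.08) |
    ell(-0.15 - j[1], 0 + j[2], 0.10 + j[3], 0.06, 0.25, 0.08)

  tab <- phantom_roi_table()
  for (nm in names(paint)) {
    m <- paint[[nm]] & brain
    if (!any(m))
      stop("grid too small to place all ROIs: cannot place ", nm)
    lab[m] <- tab$id[tab$name == nm]
  }

  base <- phantom_base_intensity()
  tmpl <- array(0, grid_shape)
  tmpl[brain] <- 1.0                      # unlabeled brain tissue
  for (nm in names(paint)) {
    id <- tab$id[tab$name == nm]
    tmpl[lab == id] <- base[[nm]]
  }

  structure(list(
    template = vol3d(tmpl, voxel_spacing, affine),
    labels = label_vol(lab, tab, voxel_spacing, affine),
    roi_table = tab,
    voxel_spacing = voxel_spacing,
    slab_thickness_mm = length(zlay) * voxel_spacing[3]),
    class = "atlas_phantom")
}

#' @export
print.atlas_phantom <- function(x, ...) {
  cat("<atlas_phantom>\n")
  print(x$template)
  cnt <- table(factor(x$labels$values, levels = x$roi_table$id,
                      labels = x$roi_table$name))
  cat("  ROI voxel counts:\n")
  print(cnt)
  invisible(x)
}

#' Specify one simulated subject
#'
#' Holds the multiplicative Mn2+ uptake factors per ROI, atrophy volume-scale
#' factors, the subject's affine misalignment, bias-field amplitude, and the
#' noise model. Identical (spec, seed) pairs reproduce bit-identical volumes.
#'
#' @param group `"control"` or `"mutant"`.
#' @param enhancement named numeric vector of multiplicative uptake factors
#'   (> 0) keyed by ROI name; unnamed ROIs default to 1. Subfield entries
#'   (CA1, DG) override their parent's factor.
#' @param atrophy named numeric vector of volume scale factors in (0, 1].
#' @param misalignment an [affine_transform()] mapping atlas world to subject
#'   world; default identity.
#' @param bias_field_amplitude smooth multiplicative shading amplitude, as a
#'   fraction of mean intensity (default 0.05).
#' @param noise_sigma noise scale in intensity units (default 0.05).
#' @param noise_model `"rician"` (magnitude MR data, default) or
#'   `"gaussian"`.
#' @param uptake_cv coefficient of variation of per-subject, per-ROI
#'   log-normal uptake variability (default 0.075), emulating the
#'   between-animal scan-to-scan variability of systemic Mn2+ uptake; with
#'   the default 20% group uptake deficit this yields standardized group
#'   effects (Cohen's d about 2-3) on the scale seen in real cohorts of
#'   this size. Set 0 for analytically exact single-subject checks.
#' @param texture_cv coefficient of variation of voxel-scale log-normal
#'   tissue texture (default 0.12), giving each ROI a continuous intensity
#'   distribution (as in real T1-weighted tissue) rather than a constant
#'   plateau. Set 0 for analytically exact single-subject checks.
#' @param seed integer RNG seed for this subject.
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(group = c("control", "mutant"),
                         enhancement = numeric(),
                         atrophy = numeric(),
                         misalignment = affine_identity(),
                         bias_field_amplitude = 0.05,
                         noise_sigma = 0.05,
                         noise_model = c("rician", "gaussian"),
                         uptake_cv = 0.075,
                         texture_cv = 0.12,
                         seed = 1L) {
  group <- match.arg(group)
  noise_model <- match.arg(noise_model)
  if (uptake_cv < 0 || texture_cv < 0)
    stop("uptake_cv and texture_cv must be >= 0")
  if (length(enhancement) && (is.null(names(enhancement)) ||
                              any(enhancement <= 0)))
    stop("enhancement factors must be a named vector with values > 0")
  if (length(atrophy) && (is.null(names(atrophy)) ||
                          any(atrophy <= 0 | atrophy > 1)))
    stop("atrophy factors must be a named vector with values in (0, 1]")
  structure(list(group = group, enhancement = enhancement, atrophy = atrophy,
                 misalignment = misalignment,
                 bias_field_amplitude = bias_field_amplitude,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 uptake_cv = uptake_cv, texture_cv = texture_cv,
                 seed = as.integer(seed)),
            class = "subject_spec")
}

#' Default cohort specifications
#'
#' Control subjects carry the uptake pattern seen with systemic Mn2+
#' (high in hippocampal subfields, hypothalamus, amygdala, septum/basal
#' forebrain, olfactory bulb and cerebellum). Mutant (tauopathy-like)
#' subjects carry a hippocampus + amygdala uptake deficit, a CA1-up /
#' DG-down subfield shift, ~30% hippocampal volume loss donated to the
#' ventricles, and mild cortical atrophy.
#'
#' @param seed subject RNG seed.
#' @return a [subject_spec()].
#' @export
control_subject_spec <- function(seed = 1L) {
  subject_spec(
    group = "control",
    enhancement = c(hippocampus = 1.5, CA1 = 1.5, DG = 1.6,
                    hypothalamus = 1.4, amygdala = 1.4,
                    septum_basal_forebrain = 1.3, olfactory_bulb = 1.4,
                    cerebellum = 1.3),
    seed = seed)
}

#' @rdname control_subject_spec
#' @param deficit fractional uptake deficit in hippocampus (subfields
#'   included) and amygdala (default 0.30, the package's default group
#'   effect size, chosen by power analysis so a 5 + 5 cohort is well
#'   powered for the activated-volume contrast at alpha = 0.05 while
#'   unaffected ROIs stay near the nominal false-positive rate).
#' @export
deficit_subject_spec <- function(deficit = 0.30, seed = 1L) {
  s <- control_subject_spec(seed = seed)
  s$group <- "mutant"
  hit <- c("hippocampus", "CA1", "DG", "amygdala")
  s$enhancement[hit] <- s$enhancement[hit] * (1 - deficit)
  s
}

#' @rdname control_subject_spec
#' @export
mutant_subject_spec <- function(seed = 1L) {
  subject_spec(
    group = "mutant",
    enhancement = c(hippocampus = 1.05, CA1 = 1.20, DG = 1.00,
                    hypothalamus = 1.4, amygdala = 0.98,
                    septum_basal_forebrain = 1.3, olfactory_bulb = 1.4,
                    cerebellum = 1.3),
    atrophy = c(hippocampus = 0.70, neocortex = 0.90),
    seed = seed)
}

# Enhancement factor per label id; parent factors applied first so subfield
# entries override them. Table order guarantees parents precede children.
enhancement_by_id <- function(enh, tab) {
  fac <- setNames(rep(1, nrow(tab)), as.character(tab$id))
  unknown <- setdiff(names(enh), tab$name)
  if (length(unknown))
    stop("unknown ROI name(s) in enhancement: ", paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    if (!nm %in% names(enh)) next
    ids <- c(tab$id[i], tab$id[!is.na(tab$parent) & tab$parent == nm])
    fac[as.character(ids)] <- enh[[nm]]
    # a named child processed later overrides the parent assignment
  }
  fac
}

# Erode an ROI's voxel set toward its centroid until the target count is
# reached. Whole erosion shells are removed while possible; the final partial
# shell removes the voxels farthest from the centroid (ties by index order)
# for determinism.
atrophy_erode <- function(lab, ids, factor, dims) {
  mask <- array(lab %in% ids, dims)
  n0 <- sum(mask)
  target <- max(1L, as.integer(round(factor * n0)))
  if (target >= n0) return(logical(length(lab)))
  if (target < 1L) stop("atrophy factor would empty the ROI")
  removed <- array(FALSE, dims)
  idx <- which(mask)
  coord <- arrayInd(idx, dims)
  cen <- colMeans(coord)
  while (sum(mask) > target) {
    inner <- cpp_morph3d(as.vector(mask), dims, FALSE)
    boundary <- which(as.vector(mask) & !inner)
    if (length(boundary) == 0L) boundary <- which(mask)  # degenerate sliver
    excess <- sum(mask) - target
    if (length(boundary) <= excess) {
      mask[boundary] <- FALSE
      removed[boundary] <- TRUE
    } else {
      bc <- arrayInd(boundary, dims)
      d2 <- rowSums((t(t(bc) - cen))^2)
      pick <- boundary[order(-d2, boundary)][seq_len(excess)]
      mask[pick] <- FALSE
      removed[pick] <- TRUE
    }
  }
  as.vector(removed)
}

# Low-order (quadratic) multiplicative bias field, centered to mean ~1 over
# the brain and scaled to the requested amplitude.
bias_field <- function(dims, brain, amplitude) {
  if (amplitude <= 0) return(array(1, dims))
  u <- lapply(dims, function(n) seq(-1, 1, length.out = n))
  X <- array(rep(u[[1]], times = prod(dims[2:3])), dims)
  Y <- array(rep(rep(u[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(u[[3]], each = prod(dims[1:2])), dims)
  cf <- runif(9, -1, 1)
  P <- cf[1] * X + cf[2] * Y + cf[3] * Z + cf[4] * X^2 + cf[5] * Y^2 +
    cf[6] * Z^2 + cf[7] * X * Y + cf[8] * X * Z + cf[9] * Y * Z
  P <- P - mean(P[brain])
  m <- max(abs(P[brain]))
  if (m > 0) P <- P / m
  1 + amplitude * P
}

#' Simulate one Mn2+-enhanced subject volume from a phantom
#'
#' Applies, in order: per-ROI multiplicative enhancement; atrophy by iterative
#' morphological erosion toward the ROI centroid with reassignment of the
#' removed voxels to a donor label (hippocampus donates to the ventricles,
#' mimicking ventricle widening; other ROIs donate to background); a smooth
#' multiplicative bias field; affine resampling by the subject's misalignment;
#' and voxel noise. The ground-truth label volume and brain mask in subject
#' space are returned alongside for oracle use.
#'
#' @param atlas an `atlas_phantom`.
#' @param spec a [subject_spec()].
#' @return list with `volume` ([vol3d()]), `labels` (ground-truth
#'   [label_vol()] in subject space), and `mask` ([brain_mask()]).
#' @export
simulate_subject <- function(atlas, spec) {
  stopifnot(inherits(atlas, "atlas_phantom"), inherits(spec, "subject_spec"))
  set.seed(spec$seed)
  dims <- dim(atlas$template$values)
  tab <- atlas$roi_table
  lab <- atlas$labels$values
  tmpl <- atlas$template$values
  base <- phantom_base_intensity()

  unknown <- setdiff(c(names(spec$enhancement), names(spec$atrophy)),
                     tab$name)
  if (length(unknown))
    stop("unknown ROI name(s): ", paste(unknown, collapse = ", "))

  # atrophy: reassign eroded voxels to the donor label and donor intensity
  for (nm in names(spec$atrophy)) {
    f <- spec$atrophy[[nm]]
    if (f >= 1) next
    ids <- c(tab$id[tab$name == nm], tab$id[!is.na(tab$parent) & tab$parent == nm])
    donor <- if (nm == "hippocampus") "ventricles" else "background"
    donor_id <- tab$id[tab$name == donor]
    removed <- atrophy_erode(as.vector(lab), ids, f, dims)
    lab[removed] <- donor_id
    tmpl[removed] <- base[[donor]]
  }

  fac <- enhancement_by_id(spec$enhancement, tab)
  if (is.null(spec$uptake_cv)) spec$uptake_cv <- 0
  if (spec$uptake_cv > 0) {
    # per-subject biological uptake variability: independent log-normal
    # factor per ROI (unit median), drawn before bias/noise in fixed order
    s <- sqrt(log(1 + spec$uptake_cv^2))
    fac <- fac * exp(rnorm(length(fac), -s^2 / 2, s))
  }
  img <- tmpl * fac[as.character(lab)]
  dim(img) <- dims

  brain <- tmpl > 0
  if (is.null(spec$texture_cv)) spec$texture_cv <- 0
  if (spec$texture_cv > 0) {
    # voxel-scale tissue texture: unit-median log-normal field over tissue
    st <- sqrt(log(1 + spec$texture_cv^2))
    tex <- array(exp(rnorm(length(img), -st^2 / 2, st)), dims)
    img[brain] <- img[brain] * tex[brain]
  }
  img <- img * bias_field(dims, brain, spec$bias_field_amplitude)

  vol <- vol3d(img, atlas$voxel_spacing, atlas$template$affine)
  labv <- label_vol(lab, tab, atlas$voxel_spacing, atlas$template$affine)

  ident <- max(abs(spec$misalignment$matrix - cbind(diag(3), 0))) < 1e-12
  if (!ident) {
    vol <- resample_volume(vol, spec$misalignment, vol, interp = "trilinear")
    labv <- warp_labels(labv, spec$misalignment, vol)
  }

  if (spec$noise_sigma > 0) {
    n <- length(vol$values)
    if (spec$noise_model == "gaussian") {
      vol$values <- vol$values + array(rnorm(n, 0, spec$noise_sigma), dims)
    } else {
      n1 <- array(rnorm(n, 0, spec$noise_sigma), dims)
      n2 <- array(rnorm(n, 0, spec$noise_sigma), dims)
      vol$values <- sqrt((vol$values + n1)^2 + n2^2)
    }
  }
  mask <- brain_mask(labv$values != 0L |
                       (if (ident) brain else
                          resample_volume(vol3d(array(as.numeric(brain), dims),
                                                atlas$voxel_spacing,
                                                atlas$template$affine),
                                          spec$misalignment, vol,
                                          interp = "nearest")$values > 0.5),
                     atlas$voxel_spacing, atlas$template$affine)
  list(volume = vol, labels = labv, mask = mask)
}

#' Draw a random within-bounds misalignment
#'
#' Bounds default to +/-1 mm translation, +/-10 degree rotation, +/-10%
#' scale and shear — small enough for the affine registration stage to
#' recover.
#'
#' @param bounds list with `translation` (mm), `rotation` (degrees),
#'   `scale`, `shear` (fractions).
#' @param center rotation center (world mm), normally the brain center.
#' @return an [affine_transform()].
#' @export
random_misalignment <- function(bounds = list(translation = 1, rotation = 10,
                                              scale = 0.1, shear = 0.1),
                                center = c(0, -2, 0)) {
  affine_from_params(
    translation = runif(3, -bounds$translation, bounds$translation),
    rotation = runif(3, -bounds$rotation, bounds$rotation),
    scale = 1 + runif(3, -bounds$scale, bounds$scale),
    shear = runif(3, -bounds$shear, bounds$shear),
    center = center)
}

#' Simulate a two-group cohort and write it to disk
#'
#' Per-subject seeds are derived deterministically from the master seed;
#' each subject receives an independent random misalignment drawn within
#' `bounds`. Volumes, ground-truth masks and label maps are written as
#' NIfTI-1 (`.nii.gz`) and indexed by a CSV manifest.
#'
#' @param atlas an `atlas_phantom`.
#' @param n_per_group subjects per group (>= 2).
#' @param control_spec,mutant_spec template [subject_spec()]s; the per-subject
#'   seed and misalignment fields are overridden.
#' @param master_seed integer master seed.
#' @param dir output directory (created if needed).
#' @param bounds misalignment bounds, see [random_misalignment()]; `NULL`
#'   keeps whatever misalignment the template specs carry.
#' @return data.frame manifest (also written to `dir/manifest.csv`) with
#'   columns subject_id, group, volume_path, mask_path, labels_path, seed.
#' @export
simulate_cohort <- function(atlas, n_per_group = 5L,
                            control_spec = control_subject_spec(),
                            mutant_spec = mutant_subject_spec(),
                            master_seed = 1L, dir = tempfile("cohort"),
                            bounds = list(translation = 1, rotation = 10,
                                          scale = 0.1, shear = 0.1)) {
  if (n_per_group < 2L) stop("need at least 2 subjects per group")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  set.seed(as.integer(master_seed))
  n <- 2L * n_per_group
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  groups <- rep(c("control", "mutant"), each = n_per_group)
  ids <- sprintf("%s%02d", ifelse(groups == "control", "C", "M"),
                 c(seq_len(n_per_group), seq_len(n_per_group)))
  ctr <- voxel_to_world(atlas$template$affine,
                        matrix((dim(atlas$template$values) - 1) / 2,
                               nrow = 1))[1, ]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tmplspec <- if (groups[i] == "control") control_spec else mutant_spec
    set.seed(seeds[i])
    mis <- if (is.null(bounds)) tmplspec$misalignment
           else random_misalignment(bounds, center = ctr)
    sp <- tmplspec
    sp$seed <- seeds[i]
    sp$misalignment <- mis
    sub <- simulate_subject(atlas, sp)
    vp <- file.path(dir, paste0(ids[i], "_vol.nii.gz"))
    mp <- file.path(dir, paste0(ids[i], "_mask.nii.gz"))
    lp <- file.path(dir, paste0(ids[i], "_labels.nii.gz"))
    write_volume(sub$volume, vp)
    write_volume(sub$mask, mp)
    write_labels(sub$labels, lp)
    rows[[i]] <- data.frame(subject_id = ids[i], group = groups[i],
                            volume_path = vp, mask_path = mp,
                            labels_path = lp, seed = seeds[i],
                            stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, rows)
  write_table(man, file.path(dir, "manifest.csv"))
  write_roi_table(atlas$roi_table, file.path(dir, "roi_table.csv"))
  man
}

#' Serialize / read a subject specification as YAML
#'
#' Documented keys: `group`, `enhancement` (ROI name -> factor map),
#' `atrophy` (ROI name -> factor map), `misalignment` (list with `matrix`,
#' 12 numbers row-major, and `direction`), `bias_field_amplitude`,
#' `noise_sigma`, `noise_model`, `uptake_cv`, `texture_cv`, `seed`.
#'
#' @param spec a [subject_spec()].
#' @param path YAML file path.
#' @return `path` (write) or a `subject_spec` (read).
#' @export
write_subject_spec <- function(spec, path) {
  stopifnot(inherits(spec, "subject_spec"))
  yaml::write_yaml(list(
    group = spec$group,
    enhancement = as.list(spec$enhancement),
    atrophy = as.list(spec$atrophy),
    misalignment = list(matrix = formatC(as.vector(t(spec$misalignment$matrix)),
                                         format = "g", digits = 17),
                        direction = spec$misalignment$direction),
    bias_field_amplitude = spec$bias_field_amplitude,
    noise_sigma = spec$noise_sigma,
    noise_model = spec$noise_model,
    uptake_cv = spec$uptake_cv,
    texture_cv = spec$texture_cv,
    seed = spec$seed), path)
  invisible(path)
}

#' @rdname write_subject_spec
#' @export
read_subject_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  mis <- if (is.null(y$misalignment)) affine_identity()
         else affine_transform(matrix(as.numeric(y$misalignment$matrix), 3, 4,
                                      byrow = TRUE),
                               y$misalignment$direction %||% "atlas_to_subject")
  subject_spec(group = y$group %||% "control",
               enhancement = unlist(y$enhancement) %||% numeric(),
               atrophy = unlist(y$atrophy) %||% numeric(),
               misalignment = mis,
               bias_field_amplitude = y$bias_field_amplitude %||% 0.05,
               noise_sigma = y$noise_sigma %||% 0.05,
               noise_model = y$noise_model %||% "rician",
               uptake_cv = y$uptake_cv %||% 0.075,
               texture_cv = y$texture_cv %||% 0.12,
               seed = y$seed %||% 1L)
}
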