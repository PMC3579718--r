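# Brute-force per-voxel oracles: plain loops over voxels, independent of the
# vectorized implementations they check.

oracle_roi_metrics <- function(zvals, labvals, ids, mask, zt, voxvol) {
  n_tot <- 0L; n_sup <- 0L; acc <- 0
  for (i in seq_along(zvals)) {
    if (!mask[i] || !(labvals[i] %in% ids)) next
    n_tot <- n_tot + 1L
    if (zvals[i] >= zt) { n_sup <- n_sup + 1L; acc <- acc + zvals[i] }
  }
  list(n_total = n_tot, n_supra = n_sup,
       mean_supra = if (n_sup > 0) acc / n_sup else NA_real_,
       active = n_sup * voxvol, vol = n_tot * voxvol)
}

oracle_rel_intensity <- function(vals, labvals, ids, mask) {
  roi_s <- 0; roi_n <- 0L; b_s <- 0; b_n <- 0L
  for (i in seq_along(vals)) {
    if (labvals[i] %in% ids) { roi_s <- roi_s + vals[i]; roi_n <- roi_n + 1L }
    if (mask[i]) { b_s <- b_s + vals[i]; b_n <- b_n + 1L }
  }
  (roi_s / roi_n) / (b_s / b_n)
}

random_instance <- function(seed) {
  set.seed(seed)
  dims <- c(16L, 16L, 16L)
  spacing <- runif(3, 0.1, 0.4)
  vals <- array(rnorm(prod(dims), 5, 2), dims)
  labs <- array(sample(0:4, prod(dims), replace = TRUE,
                       prob = c(0.4, 0.2, 0.2, 0.1, 0.1)), dims)
  tab <- data.frame(id = 0:4,
                    name = c("background", "hippocampus", "CA1", "DG", "other"),
                    parent = c(NA, NA, "hippocampus", "hippocampus", NA))
  mask <- array(runif(prod(dims)) < 0.9, dims)
  mask[1] <- TRUE
  v <- vol3d(vals, spacing)
  list(v = v,
       lab = label_vol(labs, tab, spacing, v$affine),
       mask = brain_mask(mask, spacing, v$affine))
}

test_that("roi metrics equal the brute-force oracle on random instances", {
  for (seed in 1:40) {
    inst <- random_instance(seed)
    zm <- zscore_normalize(inst$v, inst$mask)
    zt <- threshold_map(zm, 1)
    for (roi in c("hippocampus", "other", "CA1")) {
      got <- roi_metrics(zt, inst$lab, roi)
      ids <- roi_ids(inst$lab, roi)
      want <- oracle_roi_metrics(as.vector(zm$values),
                                 as.vector(inst$lab$values), ids,
                                 as.vector(inst$mask$values), 1,
                                 prod(inst$v$spacing))
      expect_identical(got$n_voxels_total, want$n_total)
      expect_identical(got$n_voxels_suprathreshold, want$n_supra)
      expect_equal(got$mean_supra_z, want$mean_supra)
      expect_equal(got$active_volume_mm3, want$active)
      expect_equal(got$roi_volume_mm3, want$vol)
    }
    # relative intensity and CA1:DG against their own loops
    ri <- relative_intensity(inst$v, inst$lab, "hippocampus", inst$mask)
    expect_equal(ri, oracle_rel_intensity(as.vector(inst$v$values),
                                          as.vector(inst$lab$values),
                                          roi_ids(inst$lab, "hippocampus"),
                                          as.vector(inst$mask$values)))
    r <- ca1_dg_ratio(inst$v, inst$lab, inst$mask)
    expect_equal(r, mean(inst$v$values[inst$lab$values == 2L]) /
                   mean(inst$v$values[inst$lab$values == 3L]),
                 tolerance = 1e-12)
    # segmented volume = count * voxel volume
    expect_equal(segmented_volume(inst$lab, "other"),
                 sum(inst$lab$values == 4L) * prod(inst$v$spacing))
  }
})

test_that("worked roi-metric example: three suprathreshold voxels", {
  dims <- c(10L, 1L, 1L)
  z <- array(0, dims); z[1:3] <- 2
  lab <- label_vol(array(1L, dims),
                   data.frame(id = 0:1, name = c("background", "roi")),
                   c(0.2, 0.2, 0.25))
  v <- vol3d(array(rnorm(10), dims), c(0.2, 0.2, 0.25))
  m <- brain_mask(array(TRUE, dims), v$spacing, v$affine)
  zm <- zscore_normalize(v, m)
  zm$values <- z                        # inject the controlled z pattern
  zt <- threshold_map(zm, 1)
  got <- roi_metrics(zt, lab, "roi")
  expect_equal(got$mean_supra_z, 2.0)
  expect_equal(got$active_volume_mm3, 3 * 0.01)
  expect_equal(got$n_voxels_total, 10L)

  # an ROI with nothing above threshold: volume 0, mean NA
  zt0 <- zt; zt0$values <- array(0, dims)
  got0 <- roi_metrics(zt0, lab, "roi")
  expect_equal(got0$active_volume_mm3, 0)
  expect_true(is.na(got0$mean_supra_z))
})

test_that("intensity ratios are invariant to global rescaling", {
  at <- tiny_atlas()
  s <- simulate_subject(at, exact_spec(enhancement = c(CA1 = 1.2, DG = 0.8)))
  m <- atlas_brain_mask(at)
  r1 <- ca1_dg_ratio(s$volume, s$labels, m)
  ri1 <- relative_intensity(s$volume, s$labels, "hippocampus", m)
  v2 <- s$volume; v2$values <- v2$values * 17.3
  expect_equal(ca1_dg_ratio(v2, s$labels, m), r1, tolerance = 1e-12)
  expect_equal(relative_intensity(v2, s$labels, "hippocampus", m), ri1,
               tolerance = 1e-12)
})

test_that("constructed subfield contrast gives the predicted ratio", {
  at <- tiny_atlas()
  # on a unit-intensity template the CA1:DG ratio is the enhancement ratio;
  # the phantom's CA1/DG base intensities are equal so they cancel
  s <- simulate_subject(at, exact_spec(enhancement = c(CA1 = 1.2, DG = 0.8)))
  m <- atlas_brain_mask(at)
  expect_equal(ca1_dg_ratio(s$volume, s$labels, m), 1.5, tolerance = 1e-6)
  # uniform image: every relative intensity is 1
  u <- vol3d(array(1, dim(at$template$values)), at$voxel_spacing,
             at$template$affine)
  expect_equal(ca1_dg_ratio(u, at$labels, m), 1.0)
  expect_equal(relative_intensity(u, at$labels, "thalamus", m), 1.0)
})

test_that("hippocampal thickness reads the slab height", {
  # synthetic slab: 6 voxels thick at 0.3 mm spacing -> 1.8 mm
  dims <- c(24L, 24L, 24L)
  lab <- array(0L, dims)
  lab[, , 13:18] <- 1L
  tab <- data.frame(id = 0:1, name = c("background", "hippocampus"))
  lv <- label_vol(lab, tab, c(0.25, 0.25, 0.3))
  th <- hippocampal_thickness(lv, ap_coordinate = 0, lateral_offset = 1.5)
  expect_equal(th$thickness_mm, 1.8)

  # asymmetric hemispheres average, per-side values retained
  ctr <- round(solve(lv$affine) %*% c(-1.5, 0, 0, 1))[1] + 1
  lab2 <- lab
  lab2[seq_len(ctr + 1), , 13:14] <- 0L   # left side thinned to 4 layers
  lv2 <- label_vol(lab2, tab, c(0.25, 0.25, 0.3))
  th2 <- hippocampal_thickness(lv2, ap_coordinate = 0, lateral_offset = 1.5)
  expect_equal(th2$thickness_left_mm, 1.2)
  expect_equal(th2$thickness_right_mm, 1.8)
  expect_equal(th2$thickness_mm, 1.5)

  # a column missing the hippocampus is NA, not zero
  lab3 <- array(0L, dims); lab3[12, 12, 13:18] <- 1L
  lv3 <- label_vol(lab3, tab, c(0.25, 0.25, 0.3))
  expect_true(is.na(hippocampal_thickness(lv3, 0, 2.5)$thickness_mm))
})

test_that("phantom slab thickness is recovered within one voxel pitch", {
  for (g in list(c(48L, 0.25), c(64L, 0.2))) {
    at <- build_atlas_phantom(g[1], g[2], geometry_seed = 2L)
    th <- hippocampal_thickness(at$labels)
    expect_lte(abs(th$thickness_mm - at$slab_thickness_mm), g[2])
  }
})

test_that("group volume ratios follow their definition", {
  expect_equal(group_volume_ratio(c(7, 7, 7), c(10, 10, 10)), 70)
  lab <- label_vol(array(rep(c(0L, 1L), c(500, 500)), c(10, 10, 10)),
                   data.frame(id = 0:1, name = c("background", "roi")),
                   rep(0.1, 3))
  expect_equal(segmented_volume(lab, "roi"), 500 * 0.001)
  expect_error(group_volume_ratio(numeric(), 1), "nonempty")
})

test_that("active volumes add over a disjoint ROI partition", {
  inst <- random_instance(99)
  zt <- threshold_map(zscore_normalize(inst$v, inst$mask), 1)
  parts <- c("hippocampus", "other")    # hippocampus includes CA1+DG
  total_ids <- unlist(lapply(parts, roi_ids, labels = inst$lab))
  whole <- sum(zt$values[inst$lab$values %in% total_ids &
                           inst$mask$values] >= 1) * prod(inst$v$spacing)
  by_part <- sum(vapply(parts, function(r)
    roi_metrics(zt, inst$lab, r)$active_volume_mm3, 0))
  expect_equal(by_part, whole)
})
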