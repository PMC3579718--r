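make_zmap_fixture <- function(values) {
  n <- length(values)
  dims <- c(n, 1L, 1L)
  v <- vol3d(array(values, dims), rep(1, 3))
  m <- brain_mask(array(TRUE, dims), v$spacing, v$affine)
  zscore_normalize(v, m)
}

test_that("z-normalization matches the two-pass arithmetic oracle", {
  zm <- make_zmap_fixture(c(2, 4, 9))
  expect_equal(zm$brain_mean, 5)
  expect_equal(zm$brain_sd, sqrt(26 / 3), tolerance = 1e-12)
  expect_equal(as.vector(zm$values),
               c(-1.01905, -0.33968, 1.35874), tolerance = 1e-4)

  # already standardized input is a fixed point
  zm2 <- make_zmap_fixture(rep(c(-1, 1), 8))
  expect_equal(as.vector(zm2$values), rep(c(-1, 1), 8), tolerance = 1e-12)

  expect_error(make_zmap_fixture(rep(3, 10)), "variance")
})

test_that("normalized maps have mean 0 and unit SD over the mask", {
  at <- tiny_atlas()
  sp <- control_subject_spec(seed = 3L)
  s <- simulate_subject(at, sp)
  zm <- zscore_normalize(s$volume, s$mask)
  z <- zm$values[zm$mask$values]
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-6)
  # out-of-mask voxels carry no z values
  expect_true(all(zm$values[!zm$mask$values] == 0))
})

test_that("normalization is invariant to affine intensity rescaling", {
  at <- tiny_atlas()
  s <- simulate_subject(at, control_subject_spec(seed = 11L))
  zm <- zscore_normalize(s$volume, s$mask)
  for (ab in list(c(3.7, 0), c(1, 12), c(0.25, -4))) {
    v2 <- s$volume
    v2$values <- ab[1] * v2$values + ab[2]
    zm2 <- zscore_normalize(v2, s$mask)
    expect_equal(zm2$values, zm$values, tolerance = 1e-6)
  }
})

test_that("thresholding zeroes sub-threshold voxels and refuses re-runs", {
  zm <- make_zmap_fixture(c(0.5, 1.0, 2.0, -3.5))
  # construct controlled z values directly
  zm$values <- array(c(0.5, 1.0, 2.0, -3.5), dim(zm$values))
  zt <- threshold_map(zm, 1)
  expect_equal(as.vector(zt$values), c(0, 1.0, 2.0, 0))
  expect_equal(zt$threshold, 1)
  expect_error(threshold_map(zt, 1), "already thresholded")
  # -Inf threshold keeps everything
  zi <- threshold_map(zm, -Inf)
  expect_equal(zi$values, zm$values)
  # all-below map becomes all zero
  za <- zm; za$values <- array(rep(0.2, 4), dim(zm$values))
  expect_true(all(threshold_map(za, 1)$values == 0))
})

test_that("suprathreshold fraction matches the normal survival oracle", {
  set.seed(42)
  dims <- c(100L, 100L, 100L)
  v <- vol3d(array(rnorm(prod(dims)), dims), rep(0.1, 3))
  m <- brain_mask(array(TRUE, dims), v$spacing, v$affine)
  zm <- zscore_normalize(v, m)
  expect_equal(suprathreshold_fraction(zm, 1), pnorm(1, lower.tail = FALSE),
               tolerance = 0.002)
  expect_equal(suprathreshold_fraction(zm, min(zm$values) - 1), 1)
  expect_equal(suprathreshold_fraction(zm, Inf), 0)
  # monotone non-increasing in the threshold
  fr <- vapply(seq(-2, 3, by = 0.5), function(t)
    suprathreshold_fraction(zm, t), 0)
  expect_true(all(diff(fr) <= 0))
  zt <- threshold_map(zm, 1)
  expect_error(suprathreshold_fraction(zt, 1), "un-thresholded")
})

test_that("suprathreshold counts are additive over a label partition", {
  at <- tiny_atlas()
  s <- simulate_subject(at, control_subject_spec(seed = 21L))
  zm <- zscore_normalize(s$volume, s$mask)
  total <- sum(zm$values[zm$mask$values] >= 1)
  ids <- sort(unique(as.vector(s$labels$values)))
  per_label <- vapply(ids, function(id) {
    sel <- s$labels$values == id & zm$mask$values
    sum(zm$values[sel] >= 1)
  }, 0)
  extra <- sum(zm$values[s$labels$values == 0L & zm$mask$values] >= 1) -
    per_label[ids == 0L]
  expect_equal(sum(per_label) + extra, total)
})

test_that("histogram census accounts for every in-mask voxel", {
  at <- tiny_atlas()
  zmaps <- lapply(1:3, function(i)
    zscore_normalize(simulate_subject(at, control_subject_spec(seed = i))$volume,
                     atlas_brain_mask(at)))
  cen <- histogram_census(zmaps, groups = c("a", "a", "b"))
  sums <- tapply(cen$counts$count, cen$counts$subject, sum)
  expect_true(all(sums == sum(atlas_brain_mask(at)$values)))

  # one subject per group: SE reported as 0
  one <- histogram_census(zmaps[1], groups = "solo")
  expect_true(all(one$summary$se_count == 0))
  # identical subjects: mean equals each, SE 0
  two <- histogram_census(zmaps[c(1, 1)], groups = c("g", "g"))
  expect_true(all(two$summary$se_count == 0))
  expect_equal(two$summary$mean_count,
               cen$counts$count[cen$counts$subject == "S1"])
})

test_that("census bin masses track analytic normal probabilities", {
  set.seed(7)
  dims <- c(60L, 60L, 60L)
  v <- vol3d(array(rnorm(prod(dims)), dims), rep(0.1, 3))
  m <- brain_mask(array(TRUE, dims), v$spacing, v$affine)
  zm <- zscore_normalize(v, m)
  edges <- seq(-4, 4, by = 0.5)
  cen <- histogram_census(list(zm), groups = "g", bin_edges = edges)
  n <- sum(m$values)
  inner <- which(edges[-length(edges)] > -4 & edges[-1] < 4)
  for (b in inner) {
    p <- pnorm(edges[b + 1]) - pnorm(edges[b])
    se3 <- 3 * sqrt(n * p * (1 - p))
    expect_lt(abs(cen$counts$count[b] - n * p), se3 + 1)
  }
})
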