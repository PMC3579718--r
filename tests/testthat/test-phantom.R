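test_that("atlas phantom construction is deterministic and complete", {
  a1 <- build_atlas_phantom(64L, 0.2, geometry_seed = 1L)
  a2 <- build_atlas_phantom(64L, 0.2, geometry_seed = 1L)
  expect_identical(a1$labels$values, a2$labels$values)
  expect_identical(a1$template$values, a2$template$values)

  # all 12 atlas ROIs + CA1 + DG + ventricles present
  present <- unique(as.vector(a1$labels$values))
  expect_gte(length(setdiff(present, 0L)), 15L)

  # subfields are subsets of the hippocampus query
  hip <- roi_mask(a1$labels, "hippocampus")
  expect_true(all(hip[a1$labels$values == 13L]))
  expect_true(all(hip[a1$labels$values == 14L]))
  # and disjoint from one another by construction (single label per voxel)
  expect_equal(sum(a1$labels$values == 13L & a1$labels$values == 14L), 0L)

  # nonzero labels sit on positive template intensity
  expect_true(all(a1$template$values[a1$labels$values != 0L] > 0))
})

test_that("too-small grids fail naming the unplaceable structure", {
  expect_error(build_atlas_phantom(16L, 0.2), "grid too small")
})

test_that("identity simulation reproduces the template exactly", {
  at <- tiny_atlas()
  s <- simulate_subject(at, exact_spec())
  expect_identical(s$volume$values, at$template$values)
  expect_identical(s$labels$values, at$labels$values)
})

test_that("ROI enhancement scales mean intensity exactly", {
  at <- tiny_atlas()
  s <- simulate_subject(at, exact_spec(enhancement = c(hippocampus = 1.5)))
  hip <- roi_mask(at$labels, "hippocampus")
  ratio <- mean(s$volume$values[hip]) / mean(at$template$values[hip])
  expect_equal(ratio, 1.5, tolerance = 1e-6)
  # other tissue untouched
  out <- at$template$values > 0 & !hip
  expect_equal(s$volume$values[out], at$template$values[out])
})

test_that("atrophy erosion hits the target voxel census", {
  at <- small_atlas()
  s <- simulate_subject(at, exact_spec(atrophy = c(hippocampus = 0.70)))
  n0 <- sum(roi_mask(at$labels, "hippocampus"))
  n1 <- sum(roi_mask(s$labels, "hippocampus"))
  expect_gte(n1 / n0, 0.67)
  expect_lte(n1 / n0, 0.73)
  # donated voxels widen the ventricles
  expect_gt(sum(s$labels$values == 15L), sum(at$labels$values == 15L))
  # non-atrophied ROI counts unchanged before resampling
  for (r in c("thalamus", "cerebellum", "amygdala"))
    expect_equal(sum(roi_mask(s$labels, r)), sum(roi_mask(at$labels, r)))
})

test_that("atrophy that would empty an ROI is refused", {
  at <- tiny_atlas()
  expect_error(subject_spec(atrophy = c(hippocampus = 0)), "atrophy")
  expect_error(simulate_subject(at, exact_spec(atrophy = c(nonexistent = 0.5))),
               "unknown ROI")
})

test_that("gaussian noise calibration recovers sigma within 2 percent", {
  at <- small_atlas()   # > 1e5 voxels
  sp <- exact_spec(seed = 9L)
  sp$noise_sigma <- 0.07
  sp$noise_model <- "gaussian"
  s <- simulate_subject(at, sp)
  resid <- s$volume$values - at$template$values
  brain <- at$template$values > 0
  expect_gt(sum(brain), 1e4)
  expect_equal(sd(resid[brain]), 0.07, tolerance = 0.02)
})

test_that("raising enhancement cannot decrease mean brain intensity", {
  at <- tiny_atlas()
  base <- simulate_subject(at, exact_spec(enhancement = c(hippocampus = 1.2)))
  up <- simulate_subject(at, exact_spec(enhancement = c(hippocampus = 1.4,
                                                        thalamus = 1.1)))
  brain <- at$template$values > 0
  expect_gte(mean(up$volume$values[brain]), mean(base$volume$values[brain]))
})

test_that("identical spec and seed give bit-identical volumes", {
  at <- tiny_atlas()
  sp <- subject_spec(enhancement = c(hippocampus = 1.3), seed = 77L)
  s1 <- simulate_subject(at, sp)
  s2 <- simulate_subject(at, sp)
  expect_identical(s1$volume$values, s2$volume$values)
  expect_identical(s1$labels$values, s2$labels$values)
})

test_that("cohort simulation writes a complete, reproducible set", {
  at <- tiny_atlas()
  d1 <- tempfile("coh1"); d2 <- tempfile("coh2")
  m1 <- simulate_cohort(at, 3L, master_seed = 7L, dir = d1)
  m2 <- simulate_cohort(at, 3L, master_seed = 7L, dir = d2)
  expect_equal(nrow(m1), 6L)
  expect_equal(sum(m1$group == "control"), 3L)
  expect_false(anyDuplicated(m1$subject_id) > 0)
  expect_true(all(file.exists(m1$volume_path)))
  # same master seed -> byte-identical image payloads
  for (i in seq_len(nrow(m1))) {
    b1 <- readBin(m1$volume_path[i], "raw", file.size(m1$volume_path[i]))
    b2 <- readBin(m2$volume_path[i], "raw", file.size(m2$volume_path[i]))
    expect_identical(b1, b2)
  }
  expect_error(simulate_cohort(at, 1L), "at least 2")
})

test_that("subject specs round-trip through YAML", {
  sp <- mutant_subject_spec(seed = 123L)
  set.seed(1)
  sp$misalignment <- random_misalignment()
  p <- tempfile(fileext = ".yaml")
  write_subject_spec(sp, p)
  r <- read_subject_spec(p)
  expect_equal(r$enhancement, sp$enhancement)
  expect_equal(r$atrophy, sp$atrophy)
  expect_equal(r$misalignment$matrix, sp$misalignment$matrix,
               tolerance = 1e-9)
  expect_identical(r$seed, sp$seed)
  expect_identical(r$noise_model, sp$noise_model)
  # same simulated output from the round-tripped spec
  at <- tiny_atlas()
  expect_identical(simulate_subject(at, r)$volume$values,
                   simulate_subject(at, sp)$volume$values)
})
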