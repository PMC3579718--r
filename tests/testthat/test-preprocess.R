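test_that("brain masking zeroes exactly the out-of-mask voxels", {
  v <- vol3d(array(5, c(6, 6, 6)), rep(0.5, 3))
  full <- brain_mask(array(TRUE, c(6, 6, 6)), v$spacing, v$affine)
  expect_identical(apply_brain_mask(v, full)$values, v$values)

  half <- array(FALSE, c(6, 6, 6)); half[1:3, , ] <- TRUE
  hm <- brain_mask(half, v$spacing, v$affine)
  out <- apply_brain_mask(v, hm)
  expect_true(all(out$values[1:3, , ] == 5))
  expect_true(all(out$values[4:6, , ] == 0))

  expect_error(brain_mask(array(FALSE, c(6, 6, 6)), v$spacing), "empty")
})

test_that("denoising is flat-field invariant and kills impulses", {
  v <- vol3d(array(3, c(8, 8, 8)), rep(0.4, 3))
  for (m in c("median3d", "aniso_diffusion"))
    expect_equal(denoise(v, m)$values, v$values, tolerance = 1e-12)

  imp <- v
  imp$values[4, 4, 4] <- 100
  expect_equal(denoise(imp, "median3d", radius = 1)$values[4, 4, 4], 3)
  expect_error(denoise(v, "median3d", radius = 0), "radius")
  expect_error(denoise(v, "nosuch"), "arg")
})

test_that("median filtering reduces gaussian noise on a phantom", {
  at <- tiny_atlas()
  sp <- exact_spec(seed = 4L); sp$noise_sigma <- 0.1; sp$noise_model <- "gaussian"
  s <- simulate_subject(at, sp)
  den <- denoise(s$volume, "median3d", radius = 1)
  brain <- at$template$values > 0
  sd_before <- sd((s$volume$values - at$template$values)[brain])
  sd_after <- sd((den$values - at$template$values)[brain])
  expect_lt(sd_after, sd_before)
})

test_that("denoising preserves the grid and the mask footprint", {
  at <- tiny_atlas()
  sp <- exact_spec(seed = 4L); sp$noise_sigma <- 0.05
  s <- simulate_subject(at, sp)
  masked <- apply_brain_mask(s$volume, s$mask)
  for (m in c("median3d", "aniso_diffusion")) {
    den <- denoise(masked, m, mask = s$mask)
    expect_identical(dim(den$values), dim(masked$values))
    expect_true(all(den$values[!s$mask$values] == 0))
  }
})

test_that("affine transforms compose, invert and serialize", {
  tr <- affine_from_params(translation = c(0.3, -0.2, 0.5),
                           rotation = c(4, -7, 2),
                           scale = c(1.05, 0.97, 1.01),
                           shear = c(0.02, -0.03, 0.01),
                           center = c(1, 2, 3))
  id <- compose_affine(tr, invert_affine(tr))
  expect_equal(unclass(id$matrix), unclass(cbind(diag(3), 0)),
               tolerance = 1e-10, ignore_attr = TRUE)
  p <- tempfile(fileext = ".txt")
  write_transform(tr, p)
  r <- read_transform(p)
  expect_equal(r$matrix, tr$matrix, tolerance = 1e-12)
  expect_identical(r$direction, tr$direction)
  expect_error(affine_transform(cbind(matrix(0, 3, 3), 1)), "invertible")
})

test_that("label warps preserve identities and respect translations", {
  at <- tiny_atlas()
  lab <- at$labels
  # identity, same grid
  w0 <- warp_labels(lab, affine_identity(), at$template)
  expect_identical(w0$values, lab$values)

  # pure translation of one voxel pitch shifts indices by one
  tr <- affine_transform(cbind(diag(3), c(at$voxel_spacing[1], 0, 0)))
  w1 <- warp_labels(lab, tr, at$template)
  d <- dim(lab$values)
  expect_identical(w1$values[2:d[1], , ], lab$values[1:(d[1] - 1), , ])
  expect_true(all(w1$values[1, , ] == 0L))

  # no new ids, ever
  set.seed(2)
  rnd <- random_misalignment(center = c(0, -2, 0))
  wr <- warp_labels(lab, rnd, at$template)
  expect_true(all(unique(as.vector(wr$values)) %in%
                    c(0L, unique(as.vector(lab$values)))))
})

test_that("warp round-trips recover each ROI almost perfectly", {
  at <- small_atlas()
  set.seed(5)
  tr <- random_misalignment(bounds = list(translation = 0.5, rotation = 5,
                                          scale = 0.05, shear = 0.05),
                            center = c(0, -2, 0))
  fwd <- warp_labels(at$labels, tr, at$template)
  back <- warp_labels(fwd, invert_affine(tr), at$template)
  for (r in c("hippocampus", "thalamus", "cerebellum")) {
    d <- dice_coefficient(roi_mask(at$labels, r), roi_mask(back, r))
    expect_gte(d, 0.98)
  }
})

test_that("scripted label edits apply in order and log provenance", {
  at <- tiny_atlas()
  lab <- at$labels
  expect_identical(adjust_labels(lab, NULL)$values, lab$values)

  vox <- which(lab$values == 6L, arr.ind = TRUE)[1:5, ]
  edits <- data.frame(i = vox[, 1], j = vox[, 2], k = vox[, 3], new_id = 5L)
  out <- adjust_labels(lab, edits)
  expect_equal(sum(out$values == 6L), sum(lab$values == 6L) - 5L)
  expect_equal(sum(out$values == 5L), sum(lab$values == 5L) + 5L)
  expect_equal(nrow(attr(out, "edit_log")), 5L)

  # overlapping edits: the later row wins
  e2 <- rbind(edits[1, ], transform(edits[1, ], new_id = 7L))
  out2 <- adjust_labels(lab, e2)
  expect_equal(out2$values[vox[1, 1], vox[1, 2], vox[1, 3]], 7L)

  expect_error(adjust_labels(lab, transform(edits, new_id = 99L)), "absent")
})

test_that("fallback Otsu mask recovers the phantom brain", {
  at <- tiny_atlas()
  sp <- exact_spec(seed = 8L); sp$noise_sigma <- 0.03
  s <- simulate_subject(at, sp)
  m <- auto_brain_mask(s$volume)
  truth <- at$template$values > 0
  expect_gte(dice_coefficient(m$values, truth), 0.95)
})
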