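# Shared fixtures: small phantoms and noise-free subject specs, built in code.

tiny_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_atlas_phantom(32L, 0.35, geometry_seed = 1L)
    cache
  }
})

small_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_atlas_phantom(48L, 0.25, geometry_seed = 1L)
    cache
  }
})

# spec with every stochastic ingredient switched off, for exact arithmetic
exact_spec <- function(enhancement = numeric(), atrophy = numeric(),
                       misalignment = affine_identity(), seed = 1L) {
  subject_spec(enhancement = enhancement, atrophy = atrophy,
               misalignment = misalignment, bias_field_amplitude = 0,
               noise_sigma = 0, noise_model = "gaussian",
               uptake_cv = 0, texture_cv = 0, seed = seed)
}

atlas_brain_mask <- function(atlas) {
  brain_mask(atlas$template$values > 0, atlas$voxel_spacing,
             atlas$template$affine)
}

# random vol3d on a given grid
random_volume <- function(dims = c(8L, 8L, 8L), spacing = 0.5, seed = 1L) {
  set.seed(seed)
  vol3d(array(rnorm(prod(dims), 10, 2), dims), rep(spacing, 3))
}
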