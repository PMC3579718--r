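# 12-parameter affine registration by multi-resolution optimization of an
# intensity similarity metric. The estimated transform maps the moving
# image's world coordinates (atlas) into the fixed image's world (subject),
# matching the pipeline's atlas-to-subject label propagation.

# Block-average downsampling by integer factor; spacing and affine adjusted
# so voxel centers stay consistent (origin shifts to the block center).
downsample_volume <- function(image, factor) {
  if (factor <= 1L) return(image)
  d <- dim(image$values)
  nd <- pmax(1L, d %/% factor)
  keep <- nd * factor
  x <- image$values[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]),
                    drop = FALSE]
  dim(x) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  vals <- apply(x, c(2, 4, 6), mean)
  shift <- image$affine[1:3, 1:3] %*% rep((factor - 1) / 2, 3)
  aff <- image$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * factor
  aff[1:3, 4] <- image$affine[1:3, 4] + shift
  vol3d(vals, image$spacing * factor, aff)
}

# Similarity metrics (maximized). All evaluate the moving image resampled
# onto the fixed grid against fixed intensities over the fixed foreground.
metric_value <- function(fixed_vals, moved_vals, sel, metric, nbins = NULL) {
  a <- fixed_vals[sel]
  b <- moved_vals[sel]
  if (length(a) < 100L) return(-Inf)
  if (is.null(nbins))                    # adaptive: ~n^(1/3), capped
    nbins <- max(8L, min(32L, as.integer(length(a)^(1 / 3))))
  if (metric == "nmse") {
    return(-mean((a - b)^2) / (stats::var(a) + 1e-12))
  }
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) return(-Inf)
  ia <- pmin(nbins, 1L + floor((a - ra[1]) / (ra[2] - ra[1]) * nbins))
  ib <- pmin(nbins, 1L + floor((b - rb[1]) / (rb[2] - rb[1]) * nbins))
  joint <- tabulate(ia + nbins * (ib - 1L), nbins * nbins) / length(a)
  pa <- tabulate(ia, nbins) / length(a)
  pb <- tabulate(ib, nbins) / length(a)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(pa); hb <- ent(pb); hab <- ent(joint)
  if (metric == "nmi") {
    if (hab <= 0) return(-Inf)
    (ha + hb) / hab
  } else {                              # correlation ratio fixed|moved
    cls <- split(a, ib)
    wv <- sum(vapply(cls, function(g) sum((g - mean(g))^2), 0))
    1 - wv / sum((a - mean(a))^2)
  }
}

# Optimization parameterization: p = (translation, rows of the linear part),
# acting about a center point: y = L (x - center) + center + t. Direct matrix
# entries avoid the rotation/scale/shear redundancy that defeats local search.
reg_params_to_transform <- function(p, center) {
  L <- matrix(p[4:12], 3, 3, byrow = TRUE)
  affine_transform(cbind(L, center + p[1:3] - L %*% center))
}

rotation_to_params <- function(translation, rotation) {
  tr <- affine_from_params(rotation = rotation)
  c(translation, as.vector(t(tr$matrix[, 1:3])))
}

intensity_centroid <- function(image) {
  w <- pmax(image$values, 0)
  s <- sum(w)
  if (s == 0) stop("image is empty after masking; cannot register")
  d <- dim(image$values)
  ii <- rep.int(seq_len(d[1]) - 1, prod(d[2:3]))
  jj <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3])
  kk <- rep(seq_len(d[3]) - 1, each = prod(d[1:2]))
  idx <- c(sum(w * ii), sum(w * jj), sum(w * kk)) / s
  voxel_to_world(image$affine, matrix(idx, nrow = 1))[1, ]
}

#' 12-parameter affine registration
#'
#' Estimates the affine transform mapping the moving image's world
#' coordinates to the fixed image's world coordinates by maximizing an
#' intensity similarity metric with a coarse-to-fine (default 4x/2x/1x)
#' schedule and Nelder–Mead optimization, initialized at identity plus an
#' intensity-centroid translation. Seedable random restarts at the coarsest
#' level guard against poor basins; the best final metric wins, ties broken
#' by first.
#'
#' @param moving,fixed [vol3d()] images (nonempty after masking).
#' @param metric `"nmi"` (normalized mutual information, default — robust to
#'   the Mn2+ enhancement contrast between atlas template and scans),
#'   `"cr"` (correlation ratio) or `"nmse"` (negative normalized MSE).
#' @param levels integer downsampling factors, coarse to fine.
#' @param restarts random restarts at the coarsest level (default 3).
#' @param seed RNG seed for the restarts.
#' @param maxit Nelder–Mead iteration budget per level.
#' @return an [affine_transform()] (direction `moving_to_fixed` semantics,
#'   tagged `atlas_to_subject`) with attributes `metric_value` and
#'   `converged`.
#' @export
register_affine <- function(moving, fixed, metric = c("nmi", "cr", "nmse"),
                            levels = c(4L, 2L, 1L), restarts = 3L,
                            seed = NULL, maxit = 400L) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  center <- intensity_centroid(fixed)
  init_t <- center - intensity_centroid(moving)
  p0 <- c(init_t, as.vector(diag(3)))

  # Per level, precompute the fixed foreground voxel indices and the index
  # map so that each metric evaluation samples only in-brain voxels.
  make_level <- function(f) {
    mv <- downsample_volume(moving, f)
    fx <- downsample_volume(fixed, f)
    sel <- which(fx$values > 0)
    idx <- arrayInd(sel, dim(fx$values)) - 1L
    a <- fx$values[sel]
    nbins <- max(8L, min(32L, as.integer(length(a)^(1 / 3))))
    ra <- range(a)
    abin <- if (ra[1] < ra[2])
      pmin(nbins, 1L + as.integer((a - ra[1]) / (ra[2] - ra[1]) * nbins))
    else rep(1L, length(a))
    list(moving = mv, fixed_vals = a, idx = idx, abin = abin, nbins = nbins,
         A_tgt = fx$affine, A_src_inv = solve(mv$affine),
         sdim = dim(mv$values), src = as.vector(mv$values))
  }
  pyramids <- lapply(levels, make_level)

  objective <- function(p, lvl) {
    tr <- reg_params_to_transform(p, center)
    M <- lvl$A_src_inv %*% solve(as_mat4(tr)) %*% lvl$A_tgt
    if (metric == "nmi") {
      m <- cpp_nmi_objective(lvl$src, lvl$sdim, lvl$idx,
                             as.vector(M[1:3, ]), lvl$abin, lvl$nbins)
    } else {
      b <- cpp_sample_points(lvl$src, lvl$sdim, lvl$idx,
                             as.vector(M[1:3, ]), 0)
      m <- metric_value(lvl$fixed_vals, b, rep(TRUE, length(b)), metric)
    }
    if (is.na(m) || !is.finite(m)) return(1e6)
    -m
  }
  pscale <- c(rep(0.5, 3), rep(0.04, 9))

  # Nelder-Mead in 12-D converges poorly from a cold simplex; each level is
  # optimized in sweeps of a rigid (translation+rotation) stage followed by
  # the full 12-parameter stage, warm-started across levels.
  # Block-cyclic descent: 3-parameter Nelder-Mead on translation, rotation,
  # scale and shear in turn (low-dimensional simplices are far more reliable
  # than one 12-D simplex), finished with a full 12-parameter polish.
  blocks <- list(1:3, 4:6, 7:9, 10:12)
  refine <- function(p, lvl, sweeps = 2L) {
    val <- NA_real_; conv <- FALSE
    for (s in seq_len(sweeps)) {
      for (b in blocks) {
        fb <- optim(p[b], function(q) {
          pp <- p; pp[b] <- q; objective(pp, lvl)
        }, method = "Nelder-Mead",
        control = list(maxit = maxit %/% 2L, parscale = pscale[b]))
        p[b] <- fb$par
      }
      ff <- optim(p, objective, lvl = lvl, method = "Nelder-Mead",
                  control = list(maxit = maxit, parscale = pscale))
      p <- ff$par; val <- ff$value; conv <- ff$convergence == 0
    }
    list(par = p, value = val, convergence = conv)
  }

  # Global initialization: rotation triples on a grid, scored at the
  # coarsest level (used for RANKING only — a 12-DOF refinement at 16^3 can
  # rank a wrong basin above the true one, so no local optimization is
  # trusted there). A diverse set of leading rotations, the identity, and
  # seeded random restarts are all refined at the mid level, whose metric is
  # reliable; the finest level polishes the winner.
  mid_lvl <- pyramids[[max(1L, length(pyramids) - 1L)]]
  rg <- seq(-10, 10, by = 5)
  rot_grid <- as.matrix(expand.grid(rg, rg, rg))
  grid_starts <- lapply(seq_len(nrow(rot_grid)), function(i)
    rotation_to_params(p0[1:3], rot_grid[i, ]))
  grid_vals <- vapply(grid_starts, objective, 0, lvl = mid_lvl)
  sel_rot <- integer()
  for (i in order(grid_vals)) {
    if (length(sel_rot) >= 5L) break
    if (all(vapply(sel_rot, function(j)
      sqrt(sum((rot_grid[i, ] - rot_grid[j, ])^2)) >= 7, TRUE)))
      sel_rot <- c(sel_rot, i)
  }
  starts <- c(list(p0), grid_starts[sel_rot])
  if (restarts > 0) {
    p_grid <- starts[[2]]
    for (r in seq_len(restarts))
      starts[[length(starts) + 1L]] <-
        p_grid + c(runif(3, -0.5, 0.5), runif(9, -0.04, 0.04))
  }

  fits <- lapply(starts, refine, lvl = mid_lvl, sweeps = 1L)
  ord <- order(vapply(fits, `[[`, 0, "value"))
  fits <- lapply(fits[ord[seq_len(min(3L, length(fits)))]],
                 function(f) refine(f$par, mid_lvl, sweeps = 1L))
  ord <- order(vapply(fits, `[[`, 0, "value"))
  fits <- fits[ord[seq_len(min(2L, length(fits)))]]
  finest <- pyramids[[length(pyramids)]]
  fits <- lapply(fits, function(f) refine(f$par, finest, sweeps = 1L))
  final <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  final <- refine(final$par, finest, sweeps = 2L)
  p <- final$par
  conv <- final$convergence
  if (!is.finite(final$value) || final$value >= 1e6)
    stop("registration metric non-finite or fields of view do not overlap")
  tr <- reg_params_to_transform(p, center)
  attr(tr, "metric_value") <- -final$value
  attr(tr, "converged") <- isTRUE(conv)
  tr
}

#' Dice overlap between two label masks
#'
#' `2|A n B| / (|A| + |B|)`, the standard agreement score for propagated
#' segmentations.
#'
#' @param a,b logical arrays (same shape).
#' @return scalar in \[0, 1\]; NaN if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
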