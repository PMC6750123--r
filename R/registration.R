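#' Registration configuration
#'
#' Controls the coarse-to-fine affine registration. Defaults follow common
#' practice for intensity-based linear registration of head MRI: a 4/2/1
#' pyramid with Gaussian pre-smoothing of sigma = factor/2 voxels per level,
#' and an intensity floor at 5% of each image's robust (99th percentile)
#' maximum to exclude air background from the ratio statistics.
#'
#' @param pyramid_factors strictly decreasing integer downsampling factors,
#'   ending at 1.
#' @param max_iterations maximum optimizer sweeps per pyramid level.
#' @param param_tolerance step size (in scaled parameter units: 1 degree =
#'   1 mm = 0.01 scale = 0.01 shear) below which a level stops.
#' @param intensity_floor_fraction fraction in (0,1) of the robust maximum
#'   defining the overlap domain of the cost.
#' @param optimizer_name label of the optimizer; only `"pattern"` (a
#'   deterministic Hooke-Jeeves pattern search) is implemented.
#' @return A list of class `medbridge_registration_config`.
#' @export
registration_config <- function(pyramid_factors = c(4L, 2L, 1L),
                                max_iterations = 100L,
                                param_tolerance = 0.01,
                                intensity_floor_fraction = 0.05,
                                optimizer_name = "pattern") {
  pyramid_factors <- as.integer(pyramid_factors)
  if (any(diff(pyramid_factors) >= 0) && length(pyramid_factors) > 1)
    stop("pyramid_factors must be strictly decreasing")
  if (pyramid_factors[length(pyramid_factors)] != 1L)
    stop("pyramid_factors must end at 1")
  if (param_tolerance <= 0) stop("param_tolerance must be positive")
  if (intensity_floor_fraction <= 0 || intensity_floor_fraction >= 1)
    stop("intensity_floor_fraction must be in (0,1)")
  if (!identical(optimizer_name, "pattern"))
    stop("unknown optimizer: ", optimizer_name)
  structure(list(pyramid_factors = pyramid_factors,
                 max_iterations = as.integer(max_iterations),
                 param_tolerance = param_tolerance,
                 intensity_floor_fraction = intensity_floor_fraction,
                 optimizer_name = optimizer_name),
            class = "medbridge_registration_config")
}

#' Resample a volume onto another volume's grid
#'
#' Evaluates `moving` at the pulled-back world position of every voxel of
#' `fixed_grid`: under the pull-back convention `t` maps fixed-space world
#' points to moving-space world points. Points falling outside the moving
#' grid receive 0. Masks are resampled with nearest-neighbour interpolation
#' (preserving the 0/1 value set); images with trilinear interpolation.
#'
#' @param moving `medbridge_volume` or `medbridge_mask` to resample.
#' @param fixed_grid volume whose grid (shape and voxel-to-world mapping)
#'   defines the output.
#' @param t pull-back `medbridge_transform` mapping fixed world points to
#'   moving world points.
#' @param interpolation `"trilinear"` or `"nearest"`; default chosen by input
#'   class.
#' @return A volume (or mask) on `fixed_grid`'s grid.
#' @export
resample <- function(moving, fixed_grid, t,
                     interpolation = if (inherits(moving, "medbridge_mask"))
                       "nearest" else "trilinear") {
  stopifnot(inherits(moving, "medbridge_volume"),
            inherits(fixed_grid, "medbridge_volume"))
  tm <- if (inherits(t, "medbridge_transform")) t$matrix else check_spatial_matrix(t)
  interpolation <- match.arg(interpolation, c("trilinear", "nearest"))
  M <- solve(moving$voxel_to_world) %*% tm %*% fixed_grid$voxel_to_world
  kern <- if (interpolation == "nearest") c_resample_nearest else c_resample_trilinear
  out <- kern(as.numeric(moving$data), moving$shape, fixed_grid$shape, M)
  arr <- array(out, dim = fixed_grid$shape)
  if (inherits(moving, "medbridge_mask") && interpolation == "nearest")
    new_mask(arr, fixed_grid$voxel_to_world)
  else
    new_volume(arr, fixed_grid$voxel_to_world)
}

robust_max <- function(x) as.numeric(quantile(x, 0.99, names = FALSE))

#' Ratio-image-uniformity cost
#'
#' The coefficient of variation sd(r)/mean(r) of the voxelwise ratio
#' r = fixed/moving over the overlap domain (voxels where both images exceed
#' `floor_fraction` times their own robust — 99th percentile — maximum).
#' Zero when the images are proportional on the domain; lower is better.
#' The standard deviation is the sample (n-1) form.
#'
#' @param fixed,moving_resampled volumes on the same grid.
#' @param floor_fraction overlap-domain intensity floor, in (0,1).
#' @return Non-negative scalar cost.
#' @export
riu_cost <- function(fixed, moving_resampled, floor_fraction = 0.05) {
  stopifnot(inherits(fixed, "medbridge_volume"),
            inherits(moving_resampled, "medbridge_volume"))
  if (!identical(fixed$shape, moving_resampled$shape))
    stop("volumes must share a grid")
  f <- as.numeric(fixed$data)
  m <- as.numeric(moving_resampled$data)
  fth <- floor_fraction * robust_max(f)
  mth <- floor_fraction * robust_max(m)
  keep <- f > fth & m > mth
  if (sum(keep) < 2L) stop("empty overlap domain in riu_cost")
  r <- f[keep] / m[keep]
  mu <- mean(r)
  if (mu <= 0) stop("non-positive mean ratio in riu_cost")
  sd(r) / mu
}

#' Center-of-mass initialization
#'
#' Pure translation aligning the intensity centroids of the two volumes (in
#' world mm), returned in the pull-back convention: resampling `moving` onto
#' `fixed`'s grid through it brings the centroids into register.
#'
#' @param moving,fixed volumes with positive total intensity.
#' @param from_space,to_space labels for the returned transform.
#' @return A translation-only `medbridge_transform` (moving -> fixed).
#' @export
center_of_mass_init <- function(moving, fixed,
                                from_space = "moving", to_space = "fixed") {
  d <- intensity_centroid(moving) - intensity_centroid(fixed)
  affine_transform(params = c(0, 0, 0, d, 1, 1, 1, 0, 0, 0),
                   from_space = from_space, to_space = to_space)
}

# smooth + subsample one pyramid level; factor 1 = untouched
pyramid_level <- function(vol, factor) {
  if (factor == 1L) return(vol)
  sm <- c_smooth_gaussian(as.numeric(vol$data), vol$shape, factor / 2)
  arr <- array(sm, dim = vol$shape)
  ix <- seq(1, vol$shape[1], by = factor)
  iy <- seq(1, vol$shape[2], by = factor)
  iz <- seq(1, vol$shape[3], by = factor)
  m <- vol$voxel_to_world %*% diag(c(factor, factor, factor, 1))
  new_volume(arr[ix, iy, iz, drop = FALSE], m)
}

# Deterministic Hooke-Jeeves pattern search (exploratory + pattern moves,
# step halving) within box bounds. Returns the accepted-cost trace
# (non-increasing).
pattern_search <- function(f, x0, step, tol, max_iter,
                           lower = rep(-Inf, length(x0)),
                           upper = rep(Inf, length(x0))) {
  fb <- function(x) if (any(x < lower | x > upper)) Inf else f(x)
  explore <- function(xc, fc) {
    for (i in seq_along(xc)) {
      xp <- xc; xp[i] <- xc[i] + step
      fp <- fb(xp)
      if (fp < fc) { xc <- xp; fc <- fp }
      else {
        xm <- xc; xm[i] <- xc[i] - step
        fm <- fb(xm)
        if (fm < fc) { xc <- xm; fc <- fm }
      }
    }
    list(x = xc, value = fc)
  }
  x <- x0
  fx <- fb(x0)
  trace <- fx
  iter <- 0L
  while (step >= tol && iter < max_iter) {
    iter <- iter + 1L
    ex <- explore(x, fx)
    if (ex$value < fx - 1e-15) {
      # pattern moves while they keep paying off
      repeat {
        xp <- pmin(pmax(2 * ex$x - x, lower), upper)
        x <- ex$x; fx <- ex$value
        trace <- c(trace, fx)
        fp <- fb(xp)
        ex2 <- explore(xp, fp)
        if (ex2$value < fx - 1e-15) ex <- ex2 else break
      }
    } else {
      step <- step / 2
    }
  }
  list(x = x, value = fx, trace = trace, iterations = iter)
}

#' Affine registration by ratio-image-uniformity minimization
#'
#' Registers `moving` to `fixed` over the full 12-parameter affine family by
#' minimizing the RIU cost with trilinear interpolation, a coarse-to-fine
#' pyramid (Gaussian pre-smoothing, subsampling), center-of-mass translation
#' initialization, and a deterministic derivative-free pattern search.
#' Rotations, scales and shears are parametrized about the fixed image's
#' intensity centroid for conditioning; the returned transform's parameter
#' vector is the canonical (origin-centred) decomposition of the final
#' matrix. There is no stochastic element: identical inputs give identical
#' results.
#'
#' @param moving,fixed volumes to register (`moving` is pulled onto `fixed`).
#' @param cfg a [registration_config()].
#' @param from_space,to_space labels for the returned transform (moving ->
#'   fixed in the pull-back sense).
#' @return A list of class `medbridge_registration` with elements
#'   `transform`, `final_cost` (the exported [riu_cost()] at the solution on
#'   the finest level), `cost_trace` (per-level accepted internal costs),
#'   `converged`.
#' @export
register_affine <- function(moving, fixed, cfg = registration_config(),
                            from_space = "moving", to_space = "fixed") {
  stopifnot(inherits(moving, "medbridge_volume"),
            inherits(fixed, "medbridge_volume"),
            inherits(cfg, "medbridge_registration_config"))
  ctr <- intensity_centroid(fixed)
  com_m <- intensity_centroid(moving)
  Tc <- diag(4); Tc[1:3, 4] <- ctr
  Tci <- diag(4); Tci[1:3, 4] <- -ctr
  base <- c(0, 0, 0, com_m - ctr, 1, 1, 1, 0, 0, 0)
  unit <- c(1, 1, 1, 1, 1, 1, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
  world_matrix <- function(x)
    Tc %*% affine_matrix_from_params(base + unit * x) %*% Tci
  floor_frac <- cfg$intensity_floor_fraction

  x <- rep(0, 12)
  cost_trace <- list()
  improved <- FALSE
  n_levels <- length(cfg$pyramid_factors)
  for (li in seq_len(n_levels)) {
    factor <- cfg$pyramid_factors[li]
    flvl <- pyramid_level(fixed, factor)
    mlvl <- pyramid_level(moving, factor)
    fvec <- as.numeric(flvl$data)
    mvec <- as.numeric(mlvl$data)
    fth <- floor_frac * robust_max(fvec)
    mth <- floor_frac * robust_max(mvec)
    fidx <- which(array(fvec, dim = flvl$shape) > fth, arr.ind = TRUE)
    fvals <- fvec[fvec > fth]
    ii <- fidx[, 1] - 1L; jj <- fidx[, 2] - 1L; kk <- fidx[, 3] - 1L
    minv <- solve(mlvl$voxel_to_world)
    fv2w <- flvl$voxel_to_world
    min_overlap <- max(32, 0.001 * prod(flvl$shape))
    cost <- function(x) {
      M <- minv %*% world_matrix(x) %*% fv2w
      acc <- c_riu_accumulate_idx(fvals, ii, jj, kk, mvec, mlvl$shape, M, mth)
      n <- acc[1]
      if (n < min_overlap) return(1e6)
      mu <- acc[2] / n
      if (mu <= 0) return(1e6)
      v <- (acc[3] - n * mu^2) / (n - 1)
      sqrt(max(v, 0)) / mu
    }
    # AIR-style degree-of-freedom schedule: rigid + scale at the coarsest
    # level, the full 12-parameter family afterwards
    active <- if (li == 1L && n_levels > 1L) 1:9 else 1:12
    x_full <- x
    cost_active <- function(xa) { x_full[active] <- xa; cost(x_full) }
    step0 <- if (li == 1L) max(factor, 4 * cfg$param_tolerance)
             else max(factor / 4, 2 * cfg$param_tolerance)
    # generous box bounds (relative to the centre-of-mass start) keep the
    # search from leaving the plausible pose regime: 30 deg, 60 mm,
    # scales in [0.6, 1.4], |shear| <= 0.2
    bound <- c(rep(30, 3), rep(60, 3), rep(40, 3), rep(20, 3))
    search <- function(x0)
      pattern_search(cost_active, x0, step = step0,
                     tol = cfg$param_tolerance,
                     max_iter = cfg$max_iterations,
                     lower = -bound[active], upper = bound[active])
    res <- search(x[active])
    if (li == 1L) {
      # the centre-of-mass start is biased along the inferior-superior axis
      # when one image carries neck/shoulder tissue the other lacks; probe a
      # few deterministic z-translation offsets and keep the best basin
      for (dz in c(-20, 20)) {
        x_alt <- x[active]
        x_alt[6] <- x_alt[6] + dz
        res_alt <- search(x_alt)
        if (res_alt$value < res$value) res <- res_alt
      }
    }
    if (res$value < res$trace[1] - 1e-15) improved <- TRUE
    x[active] <- res$x
    cost_trace[[length(cost_trace) + 1L]] <- res$trace
  }

  if (!improved) {
    init <- center_of_mass_init(moving, fixed, from_space, to_space)
    warning("optimizer failed to improve on the initialization; returning it")
    final <- tryCatch(
      riu_cost(fixed, resample(moving, fixed, init), floor_frac),
      error = function(e) NA_real_)
    return(structure(list(transform = init, final_cost = final,
                          cost_trace = cost_trace, converged = FALSE),
                     class = "medbridge_registration"))
  }

  tr <- affine_transform(matrix = world_matrix(x),
                         from_space = from_space, to_space = to_space)
  final <- riu_cost(fixed, resample(moving, fixed, tr), floor_frac)
  structure(list(transform = tr, final_cost = final,
                 cost_trace = cost_trace, converged = TRUE),
            class = "medbridge_registration")
}

#' @export
print.medbridge_registration <- function(x, ...) {
  cat(sprintf("<registration> converged: %s, final RIU cost: %.6g\n",
              x$converged, x$final_cost))
  print(x$transform)
  invisible(x)
}
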