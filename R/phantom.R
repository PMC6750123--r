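#' Phantom specification
#'
#' Parameters of the synthetic T1-like brain phantom. The default grid is
#' 96^3 voxels at 2 mm isotropic (world frame centred on the grid), small
#' enough that a full multi-mediator experiment runs in minutes; tissue means
#' follow the usual T1 contrast ordering (CSF dark, grey matter intermediate,
#' white matter bright, skull dark, neck/fat bright).
#'
#' @param grid_shape voxel counts per axis (>= 32 each).
#' @param voxel_size voxel size in mm per axis.
#' @param anatomy_seed default anatomy seed (shape jitter).
#' @param tissue_intensities named list/vector with means for `csf`, `gm`,
#'   `wm`, `skull`, `neck` (arbitrary units, pairwise distinct).
#' @param noise_sigma additive Gaussian noise SD (intensity units).
#' @param bias_field_amplitude peak fractional amplitude of the smooth
#'   multiplicative intensity non-uniformity field.
#' @param neck_extent extent (mm) of the high-intensity neck block appended
#'   below the head when a sagittal-style field of view is requested; 0
#'   disables it.
#' @return A list of class `medbridge_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         voxel_size = c(2, 2, 2),
                         anatomy_seed = 1L,
                         tissue_intensities = c(csf = 30, gm = 80, wm = 110,
                                                skull = 45, neck = 120),
                         noise_sigma = 2,
                         bias_field_amplitude = 0.1,
                         neck_extent = 40) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 32L)) stop("grid too small: need >= 32 voxels per axis")
  ti <- unlist(tissue_intensities)
  need <- c("csf", "gm", "wm", "skull", "neck")
  if (!all(need %in% names(ti))) stop("tissue_intensities needs ",
                                      paste(need, collapse = ", "))
  if (anyDuplicated(ti[need])) stop("tissue intensity means must be distinct")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 anatomy_seed = as.integer(anatomy_seed),
                 tissue_intensities = ti, noise_sigma = noise_sigma,
                 bias_field_amplitude = bias_field_amplitude,
                 neck_extent = neck_extent),
            class = "medbridge_phantom_spec")
}

# centred, axis-aligned voxel-to-world mapping
canonical_v2w <- function(grid_shape, voxel_size) {
  m <- diag(c(voxel_size, 1))
  m[1:3, 4] <- -(grid_shape - 1) / 2 * voxel_size
  m
}

# world coordinate vectors along each axis of an axis-aligned grid
grid_axes <- function(shape, v2w) {
  lapply(1:3, function(a) v2w[a, a] * (seq_len(shape[a]) - 1) + v2w[a, 4])
}

#' Generate a canonical brain phantom
#'
#' Builds a deterministic, seed-jittered synthetic head in the canonical
#' (template) space: nested smooth compartments — white-matter core, grey
#' matter shell, CSF rim (with two interior ventricles) and a skull shell —
#' on ellipsoidal surfaces whose axis lengths are jittered by +-10% per seed
#' and whose surface is perturbed by low-order directional harmonics. The
#' brain mask covers white matter, grey matter and the interior CSF
#' (ventricles), matching the mask definition used for Dice evaluation.
#' Intensities are lightly smoothed so boundaries are not aliased; the pose
#' is identity.
#'
#' @param seed integer anatomy seed; identical seeds give bit-identical
#'   output.
#' @param spec a [phantom_spec()].
#' @return A list of class `medbridge_phantom_sample`: `volume`,
#'   `brain_mask`, `true_to_canonical` (identity), plus the `spec` and the
#'   realized geometry (`geom`).
#' @export
make_canonical_brain <- function(seed, spec = phantom_spec()) {
  stopifnot(inherits(spec, "medbridge_phantom_spec"))
  shape <- spec$grid_shape
  v2w <- canonical_v2w(shape, spec$voxel_size)
  geom <- with_local_seed(seed, {
    list(center = c(0, 0, 8),
         semi = c(80, 95, 73) * runif(3, 0.9, 1.1),
         harm = pmax(pmin(rnorm(7, 0, 0.05), 0.12), -0.12),
         seed = as.integer(seed))
  })
  ax <- grid_axes(shape, v2w)
  dx <- (ax[[1]] - geom$center[1]) / geom$semi[1]
  dy <- (ax[[2]] - geom$center[2]) / geom$semi[2]
  dz <- (ax[[3]] - geom$center[3]) / geom$semi[3]
  DX <- array(rep(dx, times = shape[2] * shape[3]), dim = shape)
  DY <- array(rep(rep(dy, each = shape[1]), times = shape[3]), dim = shape)
  DZ <- array(rep(dz, each = shape[1] * shape[2]), dim = shape)
  rho0 <- sqrt(DX^2 + DY^2 + DZ^2)
  r <- pmax(rho0, 1e-9)
  ux <- DX / r; uy <- DY / r; uz <- DZ / r
  h <- geom$harm
  mod <- 1 + h[1] * ux + h[2] * uy + h[3] * uz +
    h[4] * ux * uy + h[5] * uy * uz + h[6] * ux * uz +
    h[7] * (ux^2 - uy^2)
  rho <- rho0 / pmax(mod, 0.5)

  ti <- spec$tissue_intensities
  vol <- array(0, dim = shape)
  vol[rho <= 1.0] <- ti[["skull"]]
  vol[rho <= 0.92] <- ti[["csf"]]
  vol[rho <= 0.78] <- ti[["gm"]]
  vol[rho <= 0.48] <- ti[["wm"]]
  # world coordinates, for the asymmetric interior structures
  WX <- DX * geom$semi[1] + geom$center[1]
  WY <- DY * geom$semi[2] + geom$center[2]
  WZ <- DZ * geom$semi[3] + geom$center[3]
  inside_brain <- rho <= 0.78
  ellip <- function(c0, s0)
    sqrt(((WX - c0[1]) / s0[1])^2 + ((WY - c0[2]) / s0[2])^2 +
         ((WZ - c0[3]) / s0[3])^2) <= 1
  # cerebellum-like posterior-inferior lobe (GM) with WM core, breaking the
  # head's front-back and up-down symmetry
  cb <- geom$center + c(0, -0.52 * geom$semi[2], -0.62 * geom$semi[3])
  sel <- ellip(cb, c(34, 26, 20)) & inside_brain
  vol[sel] <- ti[["gm"]]
  sel <- ellip(cb, c(20, 15, 11)) & inside_brain
  vol[sel] <- ti[["wm"]]
  # brainstem column (WM) anterior to the cerebellum
  bs <- sqrt(((WX - geom$center[1]) / 11)^2 +
             ((WY - cb[2] - 24) / 13)^2) <= 1 &
    WZ > cb[3] - 18 & WZ < geom$center[3] - 8
  vol[bs & inside_brain] <- ti[["wm"]]
  # asymmetric lateral ventricles: interior CSF, left larger than right
  vol[ellip(geom$center + c(-14, -4, 12), c(10, 26, 13))] <- ti[["csf"]]
  vol[ellip(geom$center + c(13, -8, 11), c(7, 18, 9))] <- ti[["csf"]]
  mask <- array(as.double(inside_brain), dim = shape)
  sm <- c_smooth_gaussian(as.numeric(vol), shape, 0.8)
  structure(list(volume = new_volume(array(sm, dim = shape), v2w),
                 brain_mask = new_mask(mask, v2w),
                 true_to_canonical = affine_identity("canonical", "canonical"),
                 spec = spec, geom = geom),
            class = "medbridge_phantom_sample")
}

#' @export
print.medbridge_phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom sample> %s voxels, mask fraction %.3f\n",
              paste(x$volume$shape, collapse = "x"),
              mean(x$brain_mask$data)))
  invisible(x)
}

check_pose <- function(pose) {
  pose <- check_params(pose)
  if (any(abs(pose[1:3]) > 30)) stop("pose rotation out of range (|rot| <= 30 deg)")
  if (any(abs(pose[4:6]) > 40)) stop("pose translation out of range (|trans| <= 40 mm)")
  if (any(pose[7:9] < 0.8 | pose[7:9] > 1.25))
    stop("pose scale out of range ([0.8, 1.25])")
  if (any(abs(pose[10:12]) > 0.15)) stop("pose shear out of range (|shear| <= 0.15)")
  pose
}

#' Perturb a phantom sample
#'
#' Moves the anatomy by an exact affine pose (recorded in the returned
#' sample's ground-truth transform), optionally extends the field of view
#' inferiorly in a sagittal-acquisition style with a high-intensity neck
#' block outside the brain, and adds a seeded smooth multiplicative bias
#' field and Gaussian noise. The brain mask is carried with nearest-neighbour
#' interpolation. Positive pose translations move the anatomy in the positive
#' world direction; rotations/scales/shears act about the world origin (near
#' the head centre on the canonical grid).
#'
#' @param sample a `medbridge_phantom_sample`.
#' @param pose 12 affine parameters (see [affine_transform()]) within
#'   |rot| <= 30 deg, |trans| <= 40 mm, scale in [0.8, 1.25].
#' @param fov `"same"` (keep the input grid) or `"sagittal"` (pad the grid
#'   inferiorly and insert the neck block of `spec$neck_extent` mm).
#' @param noise_sigma additive Gaussian noise SD.
#' @param bias_amplitude peak fractional amplitude of the bias field.
#' @param seed seed for noise/bias.
#' @return A new `medbridge_phantom_sample` whose `true_to_canonical` is the
#'   pose matrix composed with the input sample's ground truth.
#' @export
perturb <- function(sample, pose = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0),
                    fov = c("same", "sagittal"),
                    noise_sigma = 0, bias_amplitude = 0, seed = 1L) {
  stopifnot(inherits(sample, "medbridge_phantom_sample"))
  fov <- match.arg(fov)
  pose <- check_pose(pose)
  spec <- sample$spec
  m_pose <- affine_matrix_from_params(pose)

  src <- sample$volume
  out_shape <- src$shape
  out_v2w <- src$voxel_to_world
  if (fov == "sagittal" && spec$neck_extent > 0) {
    pad <- as.integer(ceiling(spec$neck_extent / abs(out_v2w[3, 3])))
    out_shape <- out_shape + c(0L, 0L, pad)
    shift <- diag(4); shift[3, 4] <- -pad
    out_v2w <- out_v2w %*% shift
  }
  grid <- new_volume(array(0, dim = out_shape), out_v2w)
  pullback <- solve(m_pose)  # new-sample world -> input-sample world
  vol <- resample(src, grid, pullback, interpolation = "trilinear")
  mask <- resample(sample$brain_mask, grid, pullback, interpolation = "nearest")

  n_expected <- sum(sample$brain_mask$data) * abs(det(m_pose[1:3, 1:3])) *
    abs(det(src$voxel_to_world[1:3, 1:3])) / abs(det(out_v2w[1:3, 1:3]))
  if (sum(mask$data) < 0.95 * n_expected)
    stop("brain clipped by the field of view beyond 5% of its volume")

  t_new_matrix <- m_pose %*% sample$true_to_canonical$matrix
  data <- vol$data

  if (fov == "sagittal" && spec$neck_extent > 0) {
    # neck block in canonical coordinates, carried through the pose
    geom <- sample$geom
    ax <- grid_axes(out_shape, out_v2w)
    X <- array(rep(ax[[1]], times = out_shape[2] * out_shape[3]), dim = out_shape)
    Y <- array(rep(rep(ax[[2]], each = out_shape[1]), times = out_shape[3]),
               dim = out_shape)
    Z <- array(rep(ax[[3]], each = out_shape[1] * out_shape[2]), dim = out_shape)
    inv_new <- solve(t_new_matrix)  # sample world -> canonical world
    CX <- inv_new[1, 1] * X + inv_new[1, 2] * Y + inv_new[1, 3] * Z + inv_new[1, 4]
    CY <- inv_new[2, 1] * X + inv_new[2, 2] * Y + inv_new[2, 3] * Z + inv_new[2, 4]
    CZ <- inv_new[3, 1] * X + inv_new[3, 2] * Y + inv_new[3, 3] * Z + inv_new[3, 4]
    z_top <- geom$center[3] - geom$semi[3] + 12
    in_neck <- CZ <= z_top & CZ >= z_top - 12 - spec$neck_extent &
      ((CX - geom$center[1]) / (0.55 * geom$semi[1]))^2 +
      ((CY - geom$center[2] + 10) / (0.8 * geom$semi[2]))^2 <= 1
    fill <- in_neck & data < 1
    data[fill] <- spec$tissue_intensities[["neck"]]
  }

  data <- with_local_seed(seed, {
    if (bias_amplitude > 0) {
      ax <- grid_axes(out_shape, out_v2w)
      ext <- vapply(ax, function(a) max(a) - min(a), numeric(1))
      g <- array(0, dim = out_shape)
      for (term in 1:3) {
        fr <- runif(3, 0.5, 1.5) / ext
        ph <- runif(3, 0, 2 * pi)
        g <- g + outer(outer(cos(2 * pi * fr[1] * ax[[1]] + ph[1]),
                             cos(2 * pi * fr[2] * ax[[2]] + ph[2])),
                       cos(2 * pi * fr[3] * ax[[3]] + ph[3]))
      }
      data <- data * (1 + bias_amplitude * g / max(abs(g)))
    }
    if (noise_sigma > 0)
      data <- data + array(rnorm(prod(out_shape), 0, noise_sigma),
                           dim = out_shape)
    data
  })

  structure(list(volume = new_volume(data, out_v2w),
                 brain_mask = mask,
                 true_to_canonical = affine_transform(
                   matrix = t_new_matrix,
                   from_space = sample$true_to_canonical$from_space,
                   to_space = "canonical"),
                 spec = spec, geom = sample$geom),
            class = "medbridge_phantom_sample")
}

random_pose <- function(rot = 10, trans = 15, scale = 0.1, shear = 0.05) {
  c(runif(3, -rot, rot), runif(3, -trans, trans),
    runif(3, 1 - scale, 1 + scale), runif(3, -shear, shear))
}

#' Generate a synthetic cohort: mediator library plus test subjects
#'
#' The canonical space is the template: the template image is an unperturbed,
#' noiseless phantom. Each mediator is a distinct-anatomy phantom under a
#' random pose with a sagittal-style field of view (neck block), noise and
#' bias; its exactly-known ground-truth transform back to the canonical space
#' plays the role of the pre-determined mediator-to-template matrix. Each
#' test subject is generated by further perturbing a designated mediator's
#' sample (same anatomy, additional pose/noise), and the designation is
#' recorded as ground truth — so criterion-based selection can be scored
#' against the generating mediator, and oracle Dice against the template
#' mask.
#'
#' Pose ranges (the cohort's spatial variability): rotations within +-10
#' degrees, translations within +-15 mm, scales in [0.9, 1.1], shears within
#' +-0.05, drawn uniformly.
#'
#' @param n_mediators,n_subjects cohort sizes (>= 1 each).
#' @param seed master seed; every random draw derives from it.
#' @param spec a [phantom_spec()].
#' @param subject_perturbation multiplier on the subject's extra pose ranges
#'   and noise (0 makes each subject an exact copy of its mediator).
#' @return A list with `library` (a `medbridge_library` whose entries carry
#'   masks), `subjects` (list of `medbridge_phantom_sample`s with `$id` and
#'   `$generator_id`), and `truth` (data.frame: subject_id, mediator_id).
#' @export
make_cohort <- function(n_mediators, n_subjects, seed = 7L,
                        spec = phantom_spec(),
                        subject_perturbation = 1) {
  if (n_mediators < 1L || n_subjects < 1L) stop("cohort counts must be >= 1")
  draws <- with_local_seed(seed, {
    list(anat_seeds = sample.int(100000L, n_mediators),
         med_poses = lapply(seq_len(n_mediators), function(i) random_pose()),
         med_seeds = sample.int(100000L, n_mediators),
         gen_idx = sample.int(n_mediators, n_subjects, replace = TRUE),
         subj_poses = lapply(seq_len(n_subjects), function(i)
           random_pose(rot = 10 * subject_perturbation,
                       trans = 15 * subject_perturbation,
                       scale = 0.1 * subject_perturbation,
                       shear = 0.05 * subject_perturbation)),
         subj_seeds = sample.int(100000L, n_subjects))
  })
  template_sample <- make_canonical_brain(spec$anatomy_seed, spec)
  med_samples <- vector("list", n_mediators)
  entries <- vector("list", n_mediators)
  for (i in seq_len(n_mediators)) {
    anat <- make_canonical_brain(draws$anat_seeds[i], spec)
    ms <- perturb(anat, draws$med_poses[[i]], fov = "sagittal",
                  noise_sigma = spec$noise_sigma,
                  bias_amplitude = spec$bias_field_amplitude,
                  seed = draws$med_seeds[i])
    id <- sprintf("med%02d", i)
    med_samples[[i]] <- ms
    entries[[i]] <- mediator_entry(
      id = id, volume = ms$volume,
      to_template = affine_transform(matrix = ms$true_to_canonical$matrix,
                                     from_space = id, to_space = "template"),
      mask = ms$brain_mask)
  }
  library <- mediator_library(template_sample$volume,
                              template_sample$brain_mask,
                              entries, space_label = "template")
  subjects <- vector("list", n_subjects)
  for (j in seq_len(n_subjects)) {
    gi <- draws$gen_idx[j]
    noise <- spec$noise_sigma * subject_perturbation
    ss <- perturb(med_samples[[gi]], draws$subj_poses[[j]], fov = "same",
                  noise_sigma = noise,
                  bias_amplitude = spec$bias_field_amplitude *
                    subject_perturbation,
                  seed = draws$subj_seeds[j])
    ss$id <- sprintf("sub%02d", j)
    ss$generator_id <- sprintf("med%02d", gi)
    subjects[[j]] <- ss
  }
  truth <- data.frame(
    subject_id = vapply(subjects, function(s) s$id, character(1)),
    mediator_id = vapply(subjects, function(s) s$generator_id, character(1)),
    stringsAsFactors = FALSE)
  list(library = library, subjects = subjects, truth = truth)
}
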