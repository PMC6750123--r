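test_that("phantom generation is deterministic and seed-sensitive", {
  spec <- coarse_spec()
  a1 <- make_canonical_brain(5, spec)
  a2 <- make_canonical_brain(5, spec)
  expect_identical(a1$volume$data, a2$volume$data)
  expect_identical(a1$brain_mask$data, a2$brain_mask$data)
  b <- make_canonical_brain(6, spec)
  expect_lt(dice(a1$brain_mask, b$brain_mask), 1)
  # perturbation with the same seed is also bit-identical
  pose <- c(3, -2, 5, 4, -6, 2, 1.03, 0.97, 1.01, 0.01, -0.02, 0)
  p1 <- perturb(a1, pose, fov = "sagittal", noise_sigma = 2,
                bias_amplitude = 0.1, seed = 9)
  p2 <- perturb(a1, pose, fov = "sagittal", noise_sigma = 2,
                bias_amplitude = 0.1, seed = 9)
  expect_identical(p1$volume$data, p2$volume$data)
})

test_that("default-grid brain mask fraction sits in the expected band", {
  for (s in c(1, 2, 7)) {
    b <- make_canonical_brain(s)
    frac <- mean(b$brain_mask$data)
    expect_gt(frac, 0.1)
    expect_lt(frac, 0.4)
  }
})

test_that("perturbation carries the anatomy by the stated pose", {
  spec <- coarse_spec()
  b <- make_canonical_brain(4, spec)
  # identity pose, no noise/neck: unchanged up to lattice-exact resampling
  p0 <- perturb(b, fov = "same")
  expect_lt(max(abs(p0$volume$data - b$volume$data)), 1e-6)
  # +9 mm x translation moves the mask centroid by +9 mm in world space
  p1 <- perturb(b, c(0, 0, 0, 9, 0, 0, 1, 1, 1, 0, 0, 0), fov = "same")
  cen <- function(m) {
    idx <- which(m$data > 0, arr.ind = TRUE) - 1
    colMeans(cbind(idx, 1) %*% t(m$voxel_to_world))[1:3]
  }
  shift <- cen(p1$brain_mask) - cen(b$brain_mask)
  expect_lte(max(abs(shift - c(9, 0, 0))), 2)  # half a 4 mm voxel
  # ground truth composes back to the identity
  pose <- c(4, -3, 6, 5, 2, -4, 1.04, 0.96, 1.02, 0.01, 0, -0.02)
  p2 <- perturb(b, pose, fov = "sagittal")
  inv_pose <- solve(affine_matrix_from_params(pose))
  expect_lt(max(abs(inv_pose %*% p2$true_to_canonical$matrix - diag(4))), 1e-9)
  # noiseless perturbed mask maps back onto the canonical mask
  back <- resample(p2$brain_mask, b$brain_mask, p2$true_to_canonical)
  expect_gt(dice(back, b$brain_mask), 0.95)
})

test_that("pose limits and clipping are enforced", {
  b <- make_canonical_brain(4, coarse_spec())
  expect_error(perturb(b, c(45, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0)), "rotation")
  expect_error(perturb(b, c(0, 0, 0, 50, 0, 0, 1, 1, 1, 0, 0, 0)),
               "translation")
  expect_error(perturb(b, c(0, 0, 0, 0, 0, 0, 0.5, 1, 1, 0, 0, 0)), "scale")
  # a large diagonal shift of an enlarged brain leaves the field of view
  expect_error(perturb(b, c(0, 0, 0, 40, 40, 40, 1.25, 1.25, 1.25, 0, 0, 0)),
               "clipped")
})

test_that("cohorts record recoverable ground truth", {
  spec <- coarse_spec(noise_sigma = 0, bias_field_amplitude = 0)
  cohort <- make_cohort(4, 3, seed = 13, spec = spec)
  expect_identical(length(cohort$library), 4L)
  expect_identical(nrow(cohort$truth), 3L)
  # subjects' generating mediator is recoverable by exhaustive mask Dice in
  # the template space (ground truth transforms on both sides)
  ids <- vapply(cohort$library$entries, function(e) e$id, character(1))
  med_masks_t <- lapply(cohort$library$entries, function(e)
    resample(e$mask, cohort$library$template_mask, e$to_template))
  for (j in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[j]]
    m_t <- resample(s$brain_mask, cohort$library$template_mask,
                    s$true_to_canonical$matrix)
    scores <- vapply(med_masks_t, function(mm) dice(m_t, mm), numeric(1))
    expect_identical(ids[which.max(scores)], s$generator_id)
  }
  # zero subject perturbation: subject equals its mediator sample
  c0 <- make_cohort(1, 1, seed = 3, spec = spec, subject_perturbation = 0)
  expect_lt(max(abs(c0$subjects[[1]]$volume$data -
                    c0$library$entries[[1]]$volume$data)), 1e-9)
})

test_that("cohort ground-truth transforms are mutually consistent", {
  spec <- coarse_spec(noise_sigma = 0, bias_field_amplitude = 0)
  cohort <- make_cohort(3, 2, seed = 21, spec = spec)
  for (j in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[j]]
    gi <- match(s$generator_id, vapply(cohort$library$entries,
                                       function(e) e$id, character(1)))
    e <- cohort$library$entries[[gi]]
    # true subject->mediator = T_subject %*% inverse(T_mediator); composing
    # with the mediator's to_template recovers the subject's direct truth
    t_sm <- s$true_to_canonical$matrix %*% solve(e$to_template$matrix)
    composed <- t_sm %*% e$to_template$matrix
    expect_lt(max(abs(composed - s$true_to_canonical$matrix)), 1e-9)
    # carried through the composed truth, the subject mask lands on its own
    # anatomy's canonical mask
    anat <- make_canonical_brain(s$geom$seed, spec)
    m_t <- resample(s$brain_mask, anat$brain_mask, composed)
    expect_gt(dice(m_t, anat$brain_mask), 0.95)
  }
})
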