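test_that("composition obeys the identity law and matches direct products", {
  t_ab <- random_invertible_affine("a", "b")
  ident_bc <- affine_identity("b", "c")
  left <- compose_affine(t_ab, ident_bc)
  expect_lt(max(abs(left$matrix - t_ab$matrix)), 1e-15)
  expect_identical(left$from_space, "a")
  expect_identical(left$to_space, "c")
  set.seed(14)
  for (i in 1:20) {
    t1 <- random_invertible_affine("a", "b")
    t2 <- random_invertible_affine("b", "c")
    comp <- compose_affine(t1, t2)
    expect_lt(max(abs(comp$matrix - oracle_matmul(t1$matrix, t2$matrix))),
              1e-12)
  }
  # non-chaining labels refuse to compose
  expect_error(compose_affine(random_invertible_affine("a", "b"),
                              random_invertible_affine("c", "d")), "chain")
})

test_that("multi-mediator selection finds an exact-match mediator", {
  spec <- coarse_spec(noise_sigma = 0, bias_field_amplitude = 0)
  lib <- tiny_library(3, seed = 11, spec = spec)
  # subject: a copy of the second mediator (exact-match dominance)
  subject <- lib$entries[[2]]$volume
  subject_mask <- lib$entries[[2]]$mask
  # the exact-match registration may return its already-optimal init (warns)
  sel <- suppressWarnings(run_multi_mediator(subject, lib, criterion = "ssd",
                                             subject_mask = subject_mask))
  expect_identical(sel$chosen_id, lib$entries[[2]]$id)
  df <- as.data.frame(sel)
  expect_identical(nrow(df), 3L)
  expect_identical(df$mediator_id,
                   vapply(lib$entries, function(e) e$id, character(1)))
  expect_lt(df$ssd[2], min(df$ssd[-2]) / 5)
  # MI agrees on the exact match
  expect_identical(sel$chosen_id,
                   suppressWarnings(run_multi_mediator(
                     subject, lib, criterion = "mi"))$chosen_id)
  oracle <- suppressWarnings(run_multi_mediator(
    subject, lib, criterion = "oracle_dice", subject_mask = subject_mask))
  expect_gte(max(vapply(oracle$candidates, function(cd) cd$dice_oracle,
                        numeric(1))),
             df$dice_oracle[df$mediator_id == sel$chosen_id])
  # composed transform is the exact product of its two factors
  for (cd in sel$candidates) {
    e <- lib$entries[[match(cd$mediator_id,
                            vapply(lib$entries, function(x) x$id,
                                   character(1)))]]
    expect_lt(max(abs(cd$composed$matrix -
                      cd$subject_to_mediator$matrix %*% e$to_template$matrix)),
              1e-12)
  }
})

test_that("single-entry libraries and error paths behave", {
  spec <- coarse_spec(noise_sigma = 0, bias_field_amplitude = 0)
  cohort <- make_cohort(1, 1, seed = 19, spec = spec)
  lib <- cohort$library
  s <- cohort$subjects[[1]]
  sel <- run_multi_mediator(s$volume, lib, criterion = "ssd")
  expect_identical(sel$chosen_id, lib$entries[[1]]$id)
  expect_error(run_multi_mediator(s$volume, lib, criterion = "oracle_dice"),
               "mask")
  expect_error(register_direct(new_volume(array(0, dim = c(32, 32, 32))),
                               lib), "positive")
})

test_that("direct registration of the template to itself is near-identity", {
  spec <- coarse_spec(noise_sigma = 0, bias_field_amplitude = 0)
  lib <- tiny_library(2, seed = 23, spec = spec)
  cand <- suppressWarnings(register_direct(lib$template, lib,
                                           registration_config()))
  expect_identical(cand$mediator_id, "__direct__")
  expect_lt(max(abs(cand$composed$params[1:6])), 0.3)
  expect_lt(max(abs(cand$composed$params[7:9] - 1)), 0.005)
})

test_that("apply_to_template preserves grids, binarity and known shifts", {
  spec <- coarse_spec(noise_sigma = 0, bias_field_amplitude = 0)
  cohort <- make_cohort(2, 1, seed = 31, spec = spec)
  lib <- cohort$library
  ident <- affine_identity("subject", "template")
  # identity transform, subject already on the template grid: unchanged
  out <- apply_to_template(lib$template, ident, lib)
  expect_equal(out$data, lib$template$data, tolerance = 1e-12)
  # masks stay binary through an arbitrary transform
  t1 <- affine_transform(params = c(4, -2, 3, 5, -4, 2, 1.03, 0.97, 1, 0.01,
                                    0, 0),
                         from_space = "subject", to_space = "template")
  mout <- apply_to_template(lib$template_mask, t1, lib)
  expect_s3_class(mout, "medbridge_mask")
  expect_true(all(mout$data %in% c(0, 1)))
  # a known-shift transform agrees with the analytically shifted mask
  d <- c(8, 0, 0)
  tshift <- affine_transform(params = c(0, 0, 0, d, 1, 1, 1, 0, 0, 0),
                             from_space = "subject", to_space = "template")
  shifted <- apply_to_template(lib$template_mask, tshift, lib)
  # analytic shift: move the voxel-to-world origin by -d and resample
  v2w <- lib$template_mask$voxel_to_world
  v2w[1:3, 4] <- v2w[1:3, 4] - d
  analytic <- resample(new_mask(lib$template_mask$data, v2w),
                       lib$template_mask, affine_identity())
  expect_gt(dice(shifted, analytic), 0.99)
})
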