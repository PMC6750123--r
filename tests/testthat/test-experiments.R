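# shared coarse cohort for the experiment-runner tests (computed once)
exp_cohort <- local({
  spec <- coarse_spec(noise_sigma = 1, bias_field_amplitude = 0.05)
  make_cohort(3, 3, seed = 17, spec = spec, subject_perturbation = 0.5)
})

test_that("experiment reports have the right cardinality and counting", {
  report <- run_experiment(exp_cohort$library, exp_cohort$subjects,
                           modes = c("direct", "single", "multi"),
                           criteria = c("ssd", "oracle_dice"))
  ps <- report$per_subject
  # 3 subjects x (direct + single + 2 multi criteria) rows
  expect_identical(nrow(ps), 12L)
  expect_identical(unique(ps$mediator_id[ps$mode == "single"]),
                   exp_cohort$library$entries[[1]]$id)
  for (cell in split(ps, interaction(ps$mode, ps$criterion, drop = TRUE)))
    expect_identical(sort(cell$subject_id),
                     sort(exp_cohort$truth$subject_id))
  expect_true(all(ps$dice >= 0 & ps$dice <= 1))
  # success counting at the configured threshold is exact
  sm <- report$summary
  for (i in seq_len(nrow(sm))) {
    cell <- ps[ps$mode == sm$mode[i] & ps$criterion == sm$criterion[i], ]
    expect_equal(sm$success_rate[i], mean(cell$dice > report$threshold))
    expect_equal(sm$mean_dice[i], mean(cell$dice))
  }
  # oracle dominance: its mean Dice is the best of the criteria
  multi <- sm[sm$mode == "multi", ]
  expect_gte(multi$mean_dice[multi$criterion == "oracle_dice"],
             max(multi$mean_dice[multi$criterion != "oracle_dice"]) - 1e-12)

  # histogram aggregation: counts sum to the cell size, cumulative hits 100
  sumry <- summarize_experiment(report)
  hg <- sumry$histogram
  for (cell in split(hg, interaction(hg$mode, hg$criterion, drop = TRUE))) {
    expect_equal(sum(cell$count), 3)
    expect_equal(cell$cumulative_pct[nrow(cell)], 100)
  }
})

test_that("success rates follow the 0.85 convention exactly", {
  ps <- data.frame(subject_id = c("a", "b", "c"), mode = "multi",
                   criterion = "ssd", mediator_id = "m",
                   dice = c(0.9, 0.8, 0.86))
  sm <- medbridge:::experiment_summary_table(ps, 0.85)
  expect_equal(sm$success_rate, 2 / 3)
  expect_equal(sm$mean_dice, mean(c(0.9, 0.8, 0.86)))
  ps$dice <- c(0.5, 1.0, 0.75)
  sm2 <- medbridge:::experiment_summary_table(ps, 0.85)
  expect_equal(sm2$min_dice, 0.5)
  expect_equal(sm2$max_dice, 1.0)
  expect_equal(sm2$mean_dice, 0.75)
})

test_that("experiment runs are deterministic and CSVs reproduce exactly", {
  lib <- exp_cohort$library
  subjects <- exp_cohort$subjects[1:2]
  r1 <- run_experiment(lib, subjects, modes = "multi", criteria = "ssd")
  r2 <- run_experiment(lib, subjects, modes = "multi", criteria = "ssd")
  expect_identical(r1$per_subject, r2$per_subject)
  d1 <- tempfile(); d2 <- tempfile()
  write_experiment(r1, d1)
  write_experiment(r2, d2)
  for (f in c("per_subject.csv", "summary.csv", "histogram.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("unknown modes, criteria and missing masks are rejected", {
  lib <- exp_cohort$library
  expect_error(run_experiment(lib, list(), modes = "direct"), "empty")
  s_nomask <- list(list(volume = exp_cohort$subjects[[1]]$volume,
                        brain_mask = NULL, id = "x"))
  expect_error(run_experiment(lib, s_nomask, modes = "direct"), "mask")
  expect_error(run_experiment(lib, exp_cohort$subjects, modes = "fly"))
  expect_error(run_experiment(lib, exp_cohort$subjects,
                              criteria = "nope"))
  expect_error(run_experiment(lib, exp_cohort$subjects,
                              single_mediator_id = "zz"), "unknown")
})

test_that("the CLI dispatches dice and score on files", {
  dir <- tempfile(); dir.create(dir)
  set.seed(2)
  m1 <- rand_mask(c(8, 8, 8))
  write_volume(m1, file.path(dir, "a.nii.gz"))
  write_volume(m1, file.path(dir, "b.nii.gz"))
  out <- capture.output(medbridge_cli(c("dice", "--a",
                                        file.path(dir, "a.nii.gz"),
                                        "--b", file.path(dir, "b.nii.gz"))))
  expect_equal(as.numeric(out), 1)
  v <- rand_volume(c(8, 8, 8))
  write_volume(v, file.path(dir, "v.nii.gz"))
  out2 <- capture.output(medbridge_cli(c("score", "--criterion", "mi",
                                         "--fixed", file.path(dir, "v.nii.gz"),
                                         "--moving", file.path(dir, "v.nii.gz"),
                                         "--bins", "16")))
  expect_gt(as.numeric(out2), 0)
  expect_error(medbridge_cli("frobnicate"), "unknown subcommand")
})
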