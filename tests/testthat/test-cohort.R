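test_that("baseline block has the printed target composition", {
  for (seed in c(1, 99)) {
    blk <- generate_baseline_block(seed)
    expect_length(blk, 80)
    counts <- table(blk)
    expect_equal(unname(counts[as.character(c(-30, -20, -10, 10, 20, 30))]),
                 rep(8L, 6), ignore_attr = TRUE)
    expect_equal(unname(counts["0"]), 32L, ignore_attr = TRUE)
  }
  expect_identical(generate_baseline_block(3), generate_baseline_block(3))
  b1 <- generate_baseline_block(1); b2 <- generate_baseline_block(2)
  expect_false(identical(b1, b2))
  expect_identical(sort(b1), sort(b2))
})

test_that("localization probes express the configured remap fraction", {
  # RWD-like subject: no remap expressed, noiseless probes
  cfg0 <- subject_config("RWD", remap_fraction = 0,
                         localization_noise_sd = 0, seed = 2)
  ds0 <- generate_subject(cfg0)
  expect_equal(illusion_index(ds0$localization_pre, ds0$localization_post), 0)
  expect_length(ds0$localization_pre, 10)
  expect_length(ds0$localization_post, 10)

  # full expression: the shift equals the terminal perturbation estimate
  cfg1 <- subject_config("ERR", remap_fraction = 1,
                         localization_noise_sd = 0, seed = 2)
  ds1 <- generate_subject(cfg1)
  expect_equal(illusion_index(ds1$localization_pre, ds1$localization_post),
               ds1$truth$terminal_remap)
  expect_gt(ds1$truth$terminal_remap, 6)
})

test_that("localization probes are unbiased up to pointing noise", {
  shifts <- t(vapply(1:12, function(s) {
    ds <- generate_subject(subject_config("ERR", remap_fraction = 0.5,
                                          localization_noise_sd = 2,
                                          seed = s))
    c(pre = mean(ds$localization_pre),
      shift = illusion_index(ds$localization_pre, ds$localization_post),
      expected = 0.5 * ds$truth$terminal_remap)
  }, numeric(3)))
  se_pre <- 2 / sqrt(10 * 12)
  expect_lt(abs(mean(shifts[, "pre"])), 3 * se_pre)
  se_shift <- 2 * sqrt(2 / 10) / sqrt(12)
  expect_lt(abs(mean(shifts[, "shift"] - shifts[, "expected"])),
            3 * se_shift)
})

test_that("a very wide transfer curve generalizes fully at every direction", {
  cond <- feedback_condition("ERR")
  cfg <- subject_config("ERR",
                        learner_params = learner_params(cond,
                                                        motor_noise_sd = 0),
                        generalization_width = 1e6, seed = 3)
  ds <- generate_subject(cfg)
  for (d in c(-30, -20, -10, 0, 10, 20, 30)) {
    change <- mean(ds$generalization_post$reach_deg[
      ds$generalization_post$direction_deg == d]) - d
    expect_equal(change, ds$truth$adaptation_signed, tolerance = 1e-9)
  }
  expect_equal(generalization_index(ds$generalization_pre,
                                    ds$generalization_post), 1,
               tolerance = 1e-9)
})

test_that("subject datasets round-trip through the plain-text writers", {
  ds <- generate_subject(subject_config("EPE", seed = 7))
  dir <- file.path(tempdir(), "subj7")
  write_subject_dataset(ds, dir)
  back <- read_subject_dataset(dir)
  expect_equal(back$adaptation_series$reach_deg,
               ds$adaptation_series$reach_deg, tolerance = 1e-8)
  expect_equal(back$adaptation_series$observed_deg,
               ds$adaptation_series$observed_deg, tolerance = 1e-8)
  expect_equal(back$localization_pre, ds$localization_pre,
               tolerance = 1e-12)
  expect_equal(back$generalization_post$reach_deg,
               ds$generalization_post$reach_deg, tolerance = 1e-8)
  expect_equal(back$truth$terminal_remap, ds$truth$terminal_remap,
               tolerance = 1e-12)
  expect_equal(back$truth$remap_fraction, ds$truth$remap_fraction)
  unlink(dir, recursive = TRUE)
})

test_that("a vision-reliance-coupled cohort reproduces the illusion-generalization link", {
  cohort <- generate_cohort(11, cohort_sampler("EPE", coupling = 1),
                            seed = 6)
  idx <- do.call(rbind, lapply(cohort, subject_indices))
  # EXP3 rotation is negative, so larger illusions are more negative and the
  # signed correlation with generalization breadth is negative
  cc <- cohort_correlation(idx)
  expect_lt(cc$R, 0)
  expect_equal(cc$n, 11)
  # magnitude coupling is positive by construction
  expect_gt(cohort_correlation(idx, signed = FALSE)$R, 0)
})
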