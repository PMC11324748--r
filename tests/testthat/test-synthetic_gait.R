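test_that("generation is deterministic given the seed and validates parameters", {
  p <- gait_params(seed = 42)
  r1 <- generate_recording(p)
  r2 <- generate_recording(p)
  expect_identical(r1$tracks$ventral$left_forepaw$x,
                   r2$tracks$ventral$left_forepaw$x)
  expect_identical(r1$tracks$lateral$hip$likelihood,
                   r2$tracks$lateral$hip$likelihood)
  r3 <- generate_recording(gait_params(seed = 43))
  expect_false(identical(r1$tracks$ventral$left_forepaw$x,
                         r3$tracks$ventral$left_forepaw$x))

  expect_pdssm_error(gait_params(swing_fraction = 1.2), "pdssm_parameter_error")
  expect_pdssm_error(gait_params(dropout_rate = 1), "pdssm_parameter_error")
  expect_pdssm_error(gait_params(stride_freq_fore = 90), "pdssm_parameter_error")
})

test_that("zero dropout leaves every likelihood at or above the filter threshold", {
  rec <- generate_recording(gait_params(seed = 1, dropout_rate = 0))
  for (view in names(rec$tracks))
    for (tr in rec$tracks[[view]])
      expect_true(all(tr$likelihood >= 0.25))
})

test_that("dropout rate controls the masked fraction", {
  rec <- generate_recording(gait_params(seed = 2, dropout_rate = 0.2,
                                        duration_s = 8))
  tr <- filter_low_likelihood(rec$tracks$ventral$left_forepaw)
  expect_lt(abs(mean(!tr$valid) - 0.2), 0.04)
})

test_that("noiseless 3 Hz gait is recovered by the spectral stage", {
  p <- gait_params(seed = 3, noise_sd = 0, dropout_rate = 0,
                   cycle_jitter_sd = 0, stride_freq_fore = 3,
                   stride_freq_hind = 3, duration_s = 5)
  rec <- clean_recording(generate_recording(p))
  for (paw in c("left_forepaw", "left_hindpaw")) {
    spec <- welch_psd(paw_ap_signal(rec, paw))
    expect_lte(abs(dominant_frequency(spec) - 3), spec$bin_width)
  }
})

test_that("ground truth is recovered at zero noise: frequency, amplitude, swing, posture", {
  p <- gait_params(seed = 4, noise_sd = 0, dropout_rate = 0,
                   cycle_jitter_sd = 0, stride_freq_fore = 3.5,
                   stride_freq_hind = 3.5, stride_amp = 60,
                   swing_fraction = 0.4, posture_hip_angle = 12,
                   body_yaw = 7, duration_s = 5)
  fv <- assemble_feature_vector(generate_recording(p))
  expect_equal(fv$values[["stride_freq_forepaw"]], 3.5, tolerance = 0.1 * 3.5)
  expect_equal(fv$values[["stride_amp_forepaw"]], 60, tolerance = 0.1 * 60)
  swing_frac <- fv$values[["swing_forepaw"]] /
    (fv$values[["swing_forepaw"]] + fv$values[["stance_forepaw"]])
  expect_equal(swing_frac, 0.4, tolerance = 0.05)
  expect_equal(fv$values[["hip_tb_angle"]], 12, tolerance = 0.5)
  expect_equal(fv$values[["snout_tb_angle"]], 7, tolerance = 0.5)
})

test_that("feature-recovery error grows with noise and dropout", {
  err_at <- function(noise_sd, dropout) {
    p <- gait_params(seed = 10, noise_sd = noise_sd, dropout_rate = dropout,
                     cycle_jitter_sd = 0, stride_freq_fore = 3.5,
                     stride_freq_hind = 3.5, stride_amp = 60, duration_s = 5)
    fv <- assemble_feature_vector(generate_recording(p))
    abs(fv$values[["stride_amp_forepaw"]] - 60)
  }
  errs <- c(err_at(0, 0), err_at(3, 0.05), err_at(8, 0.15))
  expect_lte(errs[1], errs[2] + 1)   # small slack: single-seed trend
  expect_lte(errs[2], errs[3] + 1)
  expect_lt(errs[1], errs[3])
})

test_that("generated tables round-trip losslessly through the DLC dialect", {
  rec <- generate_recording(gait_params(seed = 8, duration_s = 1))
  dir <- withr::local_tempdir()
  paths <- write_recording_dlc(rec, dir)
  back <- read_recording(paths[["ventral"]], paths[["lateral"]],
                         animal_id = rec$animal_id, condition = rec$condition)
  for (view in names(rec$tracks))
    for (m in names(rec$tracks[[view]])) {
      expect_equal(back$tracks[[view]][[m]]$x, rec$tracks[[view]][[m]]$x,
                   tolerance = 1e-10)
      expect_equal(back$tracks[[view]][[m]]$likelihood,
                   rec$tracks[[view]][[m]]$likelihood, tolerance = 1e-10)
    }
})

test_that("cohorts are reproducible with distinct animals per preset", {
  c1 <- generate_cohort(13, "control", seed = 5, duration_s = 1)
  c2 <- generate_cohort(13, "control", seed = 5, duration_s = 1)
  expect_length(c1, 13)
  expect_identical(vapply(c1, `[[`, "", "animal_id"),
                   vapply(c2, `[[`, "", "animal_id"))
  expect_equal(length(unique(vapply(c1, `[[`, "", "animal_id"))), 13)
  expect_identical(c1[[4]]$tracks$ventral$left_forepaw$x,
                   c2[[4]]$tracks$ventral$left_forepaw$x)
})

test_that("pd preset shifts features in the stated directions", {
  ctrl <- generate_cohort(8, "control", seed = 31)
  pd <- generate_cohort(8, "pd", seed = 32)
  f_ctrl <- do.call(rbind, lapply(ctrl, function(r) assemble_feature_vector(r)$values))
  f_pd <- do.call(rbind, lapply(pd, function(r) assemble_feature_vector(r)$values))
  expect_lt(mean(f_pd[, "stride_amp_forepaw"], na.rm = TRUE),
            mean(f_ctrl[, "stride_amp_forepaw"], na.rm = TRUE))
  expect_gt(mean(f_pd[, "hip_tb_angle"], na.rm = TRUE),
            mean(f_ctrl[, "hip_tb_angle"], na.rm = TRUE))
  expect_lt(mean(f_pd[, "stride_freq_forepaw"], na.rm = TRUE),
            mean(f_ctrl[, "stride_freq_forepaw"], na.rm = TRUE))
})

test_that("a preset swing fraction of 0.3 is recovered from the cohort", {
  pre <- cohort_preset("control")
  pre$dist$swing_fraction <- c(0.3, 0.01)
  recs <- generate_cohort(6, pre, seed = 77)
  fracs <- vapply(recs, function(r) {
    fv <- assemble_feature_vector(r)
    fv$values[["swing_forepaw"]] /
      (fv$values[["swing_forepaw"]] + fv$values[["stance_forepaw"]])
  }, numeric(1))
  expect_lt(abs(mean(fracs, na.rm = TRUE) - 0.3), 0.05)
})
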