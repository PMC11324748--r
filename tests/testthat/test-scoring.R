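# build a reference directly from a numeric matrix of control values
ref_from_values <- function(v, feature = "hip_tb_angle", estimator = "gaussian") {
  mat <- matrix(rep(v, 15), ncol = 15)
  colnames(mat) <- feature_names()
  build_control_reference(mat, estimator = estimator)
}

test_that("gaussian bands recover +/-1.96 on a large standard normal sample", {
  set.seed(101)
  ref <- ref_from_values(rnorm(1e4))
  b <- ref$features$hip_tb_angle
  expect_equal(b$lower[["95"]], -1.96, tolerance = 0.05)
  expect_equal(b$upper[["95"]], 1.96, tolerance = 0.05)
  expect_equal(b$center, 0, tolerance = 0.05)
})

test_that("empirical bands equal the brute-force percentile oracle on 1..100", {
  v <- as.numeric(1:100)
  ref <- ref_from_values(v, estimator = "empirical")
  b <- ref$features$hip_tb_angle
  expect_equal(b$lower[["68"]], unname(stats::quantile(v, 0.16)))
  expect_equal(b$upper[["68"]], unname(stats::quantile(v, 0.84)))
  expect_equal(b$lower[["99"]], unname(stats::quantile(v, 0.005)))
  expect_equal(b$upper[["99"]], unname(stats::quantile(v, 0.995)))
})

test_that("bands are nested and centered for both estimators", {
  set.seed(33)
  v <- rgamma(200, shape = 2)
  for (est in c("gaussian", "empirical")) {
    b <- ref_from_values(v, estimator = est)$features$hip_tb_angle
    expect_true(all(diff(b$lower) <= 0))   # 68 >= 95 >= 99 lower bound
    expect_true(all(diff(b$upper) >= 0))
    expect_true(all(b$lower <= b$center & b$center <= b$upper))
  }
})

test_that("degenerate and undersized control cohorts are rejected", {
  expect_pdssm_error(ref_from_values(rep(4, 13)),
                     "pdssm_degenerate_reference_error")
  expect_pdssm_error(ref_from_values(c(1, 2)),
                     "pdssm_insufficient_data_error")
})

test_that("band rule scores 0/1/2/3 by nested interval membership, inclusively", {
  set.seed(55)
  ref <- ref_from_values(rnorm(500, mean = 10, sd = 2))
  b <- ref$features$hip_tb_angle
  expect_identical(score_feature(b$center, "hip_tb_angle", ref), 0L)
  expect_identical(score_feature(b$upper[["68"]], "hip_tb_angle", ref), 0L)  # inclusive
  expect_identical(
    score_feature((b$upper[["68"]] + b$upper[["95"]]) / 2, "hip_tb_angle", ref), 1L)
  expect_identical(
    score_feature((b$upper[["95"]] + b$upper[["99"]]) / 2, "hip_tb_angle", ref), 2L)
  expect_identical(
    score_feature((b$lower[["95"]] + b$lower[["99"]]) / 2, "hip_tb_angle", ref), 2L)
  expect_identical(score_feature(b$upper[["99"]] + 1, "hip_tb_angle", ref), 3L)
  expect_identical(score_feature(b$lower[["99"]] - 1, "hip_tb_angle", ref), 3L)
  expect_pdssm_error(score_feature(NaN, "hip_tb_angle", ref),
                     "pdssm_invalid_value_error")
})

test_that("score is non-decreasing in distance from the center", {
  set.seed(66)
  ref <- ref_from_values(rnorm(500))
  center <- ref$features$hip_tb_angle$center
  for (dir in c(-1, 1)) {
    sc <- vapply(seq(0, 4, by = 0.1), function(d)
      score_feature(center + dir * d, "hip_tb_angle", ref), integer(1))
    expect_true(all(diff(sc) >= 0))
  }
})

mk_fv <- function(values, animal_id = "a1", condition = "pd") {
  v <- stats::setNames(as.numeric(values), feature_names())
  structure(list(values = v, missing = feature_names()[!is.finite(v)],
                 animal_id = animal_id, condition = condition),
            class = "feature_vector")
}

test_that("PD-SSm totals: 0 at center, 45 beyond all 99% bounds, additivity", {
  set.seed(77)
  ref <- ref_from_values(rnorm(500, 5, 1))
  b <- ref$features$hip_tb_angle
  expect_equal(compute_pdssm(mk_fv(rep(b$center, 15)), ref)$total, 0)
  expect_equal(compute_pdssm(mk_fv(rep(b$upper[["99"]] + 10, 15)), ref)$total, 45)
  one_mild <- rep(b$center, 15)
  one_mild[7] <- (b$upper[["68"]] + b$upper[["95"]]) / 2
  expect_equal(compute_pdssm(mk_fv(one_mild), ref)$total, 1)
})

test_that("total is permutation-invariant and bounded by 3 * n_scored <= 45", {
  set.seed(88)
  ref <- ref_from_values(rnorm(500))
  vals <- rnorm(15)
  sc <- compute_pdssm(mk_fv(vals), ref)
  expect_lte(sc$total, 3 * sc$n_scored)
  expect_lte(3 * sc$n_scored, 45)
  expect_equal(sum(sc$per_feature, na.rm = TRUE), sc$total)
  perm <- sample(15)
  sc2 <- compute_pdssm(mk_fv(vals[perm][order(perm)]), ref)
  expect_equal(sc2$total, sc$total)
})

test_that("missing features score NA, contribute 0 and reduce n_scored", {
  set.seed(99)
  ref <- ref_from_values(rnorm(500))
  vals <- rep(ref$features$hip_tb_angle$center, 15)
  vals[c(3, 9)] <- NA
  sc <- compute_pdssm(mk_fv(vals), ref)
  expect_equal(sc$n_scored, 13)
  expect_true(all(is.na(sc$per_feature[c(3, 9)])))
  expect_equal(sc$total, 0)
})

test_that("self-scoring calibration reproduces gaussian band coverage", {
  set.seed(123)
  v <- rnorm(1e4)
  ref <- ref_from_values(v)
  scores <- vapply(v, score_feature, integer(1),
                   feature = "hip_tb_angle", reference = ref)
  freq <- tabulate(scores + 1L, nbins = 4) / length(v)
  expect_equal(freq, c(0.68, 0.27, 0.04, 0.01), tolerance = 0.02)
})

test_that("reference JSON round-trips and preserves scoring", {
  set.seed(44)
  ref <- ref_from_values(rnorm(300, 2, 0.5))
  path <- withr::local_tempfile(fileext = ".json")
  write_reference(ref, path)
  back <- read_reference(path)
  expect_equal(back$n_controls, ref$n_controls)
  expect_equal(back$features$hip_tb_angle$upper, ref$features$hip_tb_angle$upper)
  v <- 2.9
  expect_identical(score_feature(v, "snout_tb_angle", back),
                   score_feature(v, "snout_tb_angle", ref))
})

test_that("feature assembly yields all 15 features on a healthy recording", {
  rec <- generate_recording(gait_params(seed = 5))
  fv <- assemble_feature_vector(rec)
  expect_identical(names(fv$values), feature_names())
  expect_length(fv$values, 15)
  expect_length(fv$missing, 0)
})

test_that("a non-stepping hindpaw degrades to missing hindpaw stride features", {
  rec <- generate_recording(gait_params(seed = 6, noise_sd = 0, dropout_rate = 0))
  n <- length(rec$tracks$ventral$left_hindpaw$x)
  rec$tracks$ventral$left_hindpaw <- marker_track(
    "left_hindpaw", "ventral", rep(220, n), rep(102, n), rep(1, n),
    frame_rate = rec$frame_rate)
  fv <- assemble_feature_vector(rec)
  expect_true(all(c("swing_hindpaw", "stance_hindpaw", "stride_freq_hindpaw",
                    "stride_amp_hindpaw") %in% fv$missing))
  expect_false(any(grepl("forepaw", fv$missing)))
  expect_length(fv$values, 15)
})

test_that("cohort scoring: controls score low against their own reference", {
  ctrl <- generate_cohort(13, "control", seed = 201)
  fvs <- lapply(ctrl, assemble_feature_vector)
  ref <- build_control_reference(fvs)
  tab <- score_cohort(ctrl, ref)
  expect_equal(nrow(tab), 13)
  expect_lt(mean(tab$total), 15)
  per_feat <- unlist(tab[, feature_names()])
  expect_gt(mean(per_feat == 0, na.rm = TRUE), 0.5)
  expect_warning(empty <- score_cohort(list(), ref), "empty cohort")
  expect_equal(nrow(empty), 0)
})
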