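#' The fifteen canonical gait feature names
#'
#' Three classes: body pose / body rotation (hip-tailbase angle,
#' snout-tailbase angle, left paw distance), spectral (dominant frequency
#' and its amplitude per left paw) and stride (swing, stance, stride
#' frequency, stride amplitude per left paw).
#'
#' @return Character vector of length 15.
#' @export
feature_names <- function() c(
  "hip_tb_angle", "snout_tb_angle", "left_paw_distance",
  "dom_freq_forepaw", "dom_freq_hindpaw",
  "dom_amp_forepaw", "dom_amp_hindpaw",
  "swing_forepaw", "swing_hindpaw",
  "stance_forepaw", "stance_hindpaw",
  "stride_freq_forepaw", "stride_freq_hindpaw",
  "stride_amp_forepaw", "stride_amp_hindpaw")

#' Extract the 15-feature gait vector from a recording
#'
#' Cleans the recording (likelihood masking at `threshold`, linear gap
#' interpolation), then runs the pose, spectral and stride stages. A feature
#' whose computation fails for lack of data (e.g. a non-stepping paw with
#' fewer than two stride peaks) is reported in `missing` rather than
#' aborting the recording; validation errors (absent markers) propagate.
#'
#' @param rec A [recording].
#' @param threshold Likelihood cutoff (default 0.25).
#' @param fmax Spectral frequency cap in Hz (default 10).
#' @param summary_stat Frame-series reducer, `"mean"` or `"median"`.
#' @param advance_sign Belt-direction sign for swing/stance labelling.
#' @return An object of class `feature_vector`: named numeric vector of the
#'   15 features (`NA` where missing) with `missing`, `animal_id` and
#'   `condition` attributes accessible as list fields.
#' @export
assemble_feature_vector <- function(rec, threshold = 0.25, fmax = 10,
                                    summary_stat = "mean", advance_sign = 1) {
  rec <- clean_recording(rec, threshold)
  values <- stats::setNames(rep(NA_real_, 15), feature_names())
  grab <- function(expr) tryCatch(expr, pdssm_insufficient_data_error = function(e) NA_real_,
                                  pdssm_insufficient_strides_error = function(e) NA_real_,
                                  pdssm_no_dominant_frequency_error = function(e) NA_real_)

  values[["hip_tb_angle"]] <-
    grab(summarize_series(hip_tailbase_angle_series(rec), summary_stat))
  values[["snout_tb_angle"]] <-
    grab(summarize_series(snout_tailbase_angle_series(rec), summary_stat))
  values[["left_paw_distance"]] <-
    grab(summarize_series(left_paw_distance_series(rec), summary_stat))

  for (paw in c("forepaw", "hindpaw")) {
    sig <- paw_ap_signal(rec, paste0("left_", paw))
    spec <- grab(welch_psd(sig, fmax = fmax))
    if (!is.list(spec)) spec <- NULL
    if (!is.null(spec)) {
      values[[paste0("dom_freq_", paw)]] <- grab(dominant_frequency(spec))
      values[[paste0("dom_amp_", paw)]] <- grab(dominant_amplitude(spec))
    }
    f_dom <- values[[paste0("dom_freq_", paw)]]
    peaks <- detect_stride_peaks(sig, f_dom = if (is.na(f_dom)) NULL else f_dom)
    strides <- grab(segment_strides(sig, peaks, paw = paste0("left_", paw),
                                    advance_sign = advance_sign))
    if (is.list(strides)) {
      sm <- stride_summary(strides)
      values[[paste0("swing_", paw)]] <- sm$mean_swing_s
      values[[paste0("stance_", paw)]] <- sm$mean_stance_s
      values[[paste0("stride_freq_", paw)]] <- sm$mean_frequency_hz
      values[[paste0("stride_amp_", paw)]] <- sm$mean_amplitude
    }
  }

  structure(list(values = values,
                 missing = names(values)[is.na(values)],
                 animal_id = rec$animal_id, condition = rec$condition),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s [%s]: %d/15 features",
              x$animal_id, x$condition, 15 - length(x$missing)))
  if (length(x$missing) > 0)
    cat(sprintf(" (missing: %s)", paste(x$missing, collapse = ", ")))
  cat("\n")
  print(round(x$values, 3))
  invisible(x)
}

# z multipliers for the gaussian 68/95/99% central intervals
BAND_LEVELS <- c("68", "95", "99")
BAND_Z <- c(`68` = 1.000, `95` = 1.960, `99` = 2.576)

#' Estimate per-feature control confidence bands
#'
#' Builds the scoring reference from a healthy control cohort: for each
#' feature, nested central 68/95/99% intervals. The gaussian estimator
#' (default) uses mean +/- z * sd with z = 1.000, 1.960, 2.576 -- the
#' appropriate choice for small cohorts, where extreme empirical
#' percentiles are undefined. The empirical estimator uses equal-tailed
#' sample percentiles and suits large cohorts. Nesting (68% interval inside
#' 95% inside 99%) holds by construction and is enforced.
#'
#' @param controls List of [assemble_feature_vector()] results from control
#'   animals (one per animal), or a numeric matrix/data frame with one row
#'   per animal and the 15 canonical feature columns.
#' @param estimator `"gaussian"` (default) or `"empirical"`.
#' @param min_controls Minimum non-missing control values per feature
#'   (default 3).
#' @return An object of class `control_reference`: per feature, `center`
#'   and a `lower`/`upper` pair per band level, plus `estimator` and
#'   `n_controls`.
#' @export
build_control_reference <- function(controls, estimator = c("gaussian", "empirical"),
                                    min_controls = 3) {
  estimator <- match.arg(estimator)
  mat <- feature_matrix(controls)
  ref <- list()
  for (f in colnames(mat)) {
    v <- mat[, f]
    v <- v[is.finite(v)]
    if (length(v) < min_controls)
      insufficient_data_error(sprintf(
        "feature '%s': %d control value(s); need >= %d", f, length(v), min_controls))
    if (stats::sd(v) == 0)
      pdssm_error("pdssm_degenerate_reference_error", sprintf(
        "feature '%s' has zero variance in the control cohort", f))
    center <- mean(v)
    if (estimator == "gaussian") {
      s <- stats::sd(v)
      lower <- center - BAND_Z * s
      upper <- center + BAND_Z * s
    } else {
      lv <- as.numeric(BAND_LEVELS) / 100
      lower <- stats::quantile(v, (1 - lv) / 2, names = FALSE)
      upper <- stats::quantile(v, (1 + lv) / 2, names = FALSE)
    }
    # enforce nesting against numerical quirks
    lower <- cummin(lower)
    upper <- cummax(upper)
    ref[[f]] <- list(center = center,
                     lower = stats::setNames(lower, BAND_LEVELS),
                     upper = stats::setNames(upper, BAND_LEVELS))
  }
  structure(list(features = ref, estimator = estimator, n_controls = nrow(mat)),
            class = "control_reference")
}

feature_matrix <- function(controls) {
  fn <- feature_names()
  if (is.matrix(controls) || is.data.frame(controls)) {
    mat <- as.matrix(controls[, fn, drop = FALSE])
  } else {
    mat <- do.call(rbind, lapply(controls, function(fv) fv$values[fn]))
  }
  colnames(mat) <- fn
  mat
}

#' Score one feature value against the control bands
#'
#' Maps a value's position among the nested control intervals to an ordinal
#' severity level: 0 inside the 68% interval, 1 inside 95% but outside 68%,
#' 2 inside 99% but outside 95%, 3 beyond the 99% bounds. Membership is
#' two-sided and inclusive at the bounds.
#'
#' @param value Feature value (finite scalar).
#' @param feature Canonical feature name.
#' @param reference A `control_reference`.
#' @return Integer severity in `0:3`.
#' @export
score_feature <- function(value, feature, reference) {
  if (!is.finite(value))
    pdssm_error("pdssm_invalid_value_error",
                sprintf("non-finite value for feature '%s'", feature))
  b <- reference$features[[feature]]
  if (is.null(b))
    validation_error(sprintf("reference has no bands for feature '%s'", feature))
  for (i in seq_along(BAND_LEVELS)) {
    if (value >= b$lower[i] && value <= b$upper[i]) return(i - 1L)
  }
  3L
}

#' Compute the PD-SSm severity score
#'
#' Sums the per-feature ordinal severities over the 15 gait features. With
#' 15 features scored 0-3 the maximum attainable total is 45. Missing
#' features contribute 0 and are disclosed through `n_scored`, keeping
#' totals comparable across recordings while flagging reduced support.
#'
#' @param features A `feature_vector`.
#' @param reference A `control_reference` covering all non-missing features.
#' @return An object of class `severity_score`: `per_feature` (named
#'   integer vector, `NA` for missing), `total` in `[0, 45]`, `n_scored`,
#'   and the recording metadata.
#' @export
compute_pdssm <- function(features, reference) {
  fn <- feature_names()
  per <- stats::setNames(rep(NA_integer_, 15), fn)
  for (f in fn) {
    v <- features$values[[f]]
    if (is.finite(v)) per[[f]] <- score_feature(v, f, reference)
  }
  structure(list(per_feature = per,
                 total = sum(per, na.rm = TRUE),
                 n_scored = sum(!is.na(per)),
                 animal_id = features$animal_id,
                 condition = features$condition),
            class = "severity_score")
}

#' @export
print.severity_score <- function(x, ...) {
  cat(sprintf("<severity_score> %s [%s]: PD-SSm = %d/45 (%d features scored)\n",
              x$animal_id, x$condition, x$total, x$n_scored))
  invisible(x)
}

#' Score a cohort of recordings
#'
#' Runs feature extraction and PD-SSm scoring on each recording; failures
#' are logged as warnings and the run continues.
#'
#' @param recordings List of [recording] objects.
#' @param reference A `control_reference`.
#' @param ... Passed to [assemble_feature_vector()].
#' @return Tidy data frame: `animal_id`, `condition`, one column per
#'   feature score, `total`, `n_scored`.
#' @export
score_cohort <- function(recordings, reference, ...) {
  fn <- feature_names()
  empty <- stats::setNames(
    data.frame(matrix(integer(0), ncol = 15)), fn)
  empty <- cbind(data.frame(animal_id = character(0), condition = character(0)),
                 empty, data.frame(total = integer(0), n_scored = integer(0)))
  if (length(recordings) == 0) {
    warning("empty cohort: nothing to score")
    return(empty)
  }
  rows <- lapply(recordings, function(rec) {
    tryCatch({
      sc <- compute_pdssm(assemble_feature_vector(rec, ...), reference)
      cbind(data.frame(animal_id = sc$animal_id, condition = sc$condition),
            as.data.frame(as.list(sc$per_feature)),
            data.frame(total = sc$total, n_scored = sc$n_scored))
    }, error = function(e) {
      warning(sprintf("recording '%s' failed: %s", rec$animal_id,
                      conditionMessage(e)))
      NULL
    })
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Serialize a control reference to JSON
#'
#' @param reference A `control_reference`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  jsonlite::write_json(
    list(estimator = reference$estimator, n_controls = reference$n_controls,
         features = reference$features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a control reference from JSON
#'
#' @param path JSON path written by [write_reference()].
#' @return A `control_reference`.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) format_error(sprintf("reference file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- lapply(j$features, function(b) list(
    center = b$center,
    lower = stats::setNames(unlist(b$lower), BAND_LEVELS),
    upper = stats::setNames(unlist(b$upper), BAND_LEVELS)))
  structure(list(features = feats, estimator = j$estimator,
                 n_controls = j$n_controls),
            class = "control_reference")
}
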