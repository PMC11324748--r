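#' Construct a frame series
#'
#' A per-frame scalar series (angle in degrees or distance in pixels)
#' aligned to the source tracks, carrying the frame rate and the mask of
#' frames whose inputs were imputed.
#'
#' @param values Numeric vector, one value per frame.
#' @param frame_rate Frames per second.
#' @param imputed Logical vector aligned to `values`.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(values, frame_rate, imputed = NULL) {
  if (is.null(imputed)) imputed <- rep(FALSE, length(values))
  if (length(imputed) != length(values))
    validation_error("imputed mask must align with values")
  structure(list(values = as.numeric(values), frame_rate = frame_rate,
                 imputed = as.logical(imputed)),
            class = "frame_series")
}

#' Angle deviation of a segment from horizontal
#'
#' Returns the unsigned deviation of the line through two points from the
#' image x-axis (assumed parallel to belt travel), folded into \[0, 90\]
#' degrees. The fold makes the angle invariant to swapping the endpoints
#' and to the unstated sign convention of a "deviation"; the signed angle in
#' (-90, 90\] is available via `signed = TRUE` for diagnostics.
#'
#' @param p_from,p_to Numeric length-2 points `(x, y)` in pixels, or equal
#'   length vectors/matrices of such points (`cbind(x, y)`).
#' @param signed Return the signed deviation instead of its magnitude.
#' @return Angle(s) in degrees.
#' @export
angle_from_horizontal <- function(p_from, p_to, signed = FALSE) {
  p_from <- matrix(p_from, ncol = 2)
  p_to <- matrix(p_to, ncol = 2)
  dx <- p_to[, 1] - p_from[, 1]
  dy <- p_to[, 2] - p_from[, 2]
  if (any(dx == 0 & dy == 0))
    validation_error("angle undefined: coincident points")
  a <- atan2(dy, dx) * 180 / pi        # (-180, 180]
  a <- a %% 180                        # [0, 180): line direction, not ray
  s <- ifelse(a > 90, a - 180, a)      # signed deviation in (-90, 90]
  if (signed) s else abs(s)
}

two_marker_series <- function(rec, view, from, to, signed = FALSE) {
  a <- get_track(rec, view, from)
  b <- get_track(rec, view, to)
  if (any(!a$valid) || any(!b$valid))
    validation_error(sprintf(
      "tracks '%s'/'%s' contain masked samples; run clean_recording() first",
      from, to))
  frame_series(
    angle_from_horizontal(cbind(a$x, a$y), cbind(b$x, b$y), signed = signed),
    frame_rate = rec$frame_rate,
    imputed = a$imputed | b$imputed)
}

#' Hip-to-tailbase posture angle series (lateral plane)
#'
#' Per-frame deviation of the hip-to-tailbase line from horizontal in the
#' side view, in degrees. An elevated angle reflects the hunched posture of
#' parkinsonian animals.
#'
#' @param rec A cleaned, gap-filled [recording].
#' @param signed Keep the sign of the deviation (default folds to \[0, 90\]).
#' @return A [frame_series] in degrees; a frame is flagged imputed if either
#'   input sample was imputed.
#' @export
hip_tailbase_angle_series <- function(rec, signed = FALSE)
  two_marker_series(rec, "lateral", "hip", "tailbase", signed = signed)

#' Snout-to-tailbase body rotation angle series (ventral plane)
#'
#' Per-frame deviation of the snout-to-tailbase body axis from the belt
#' direction in the bottom-up view, in degrees (yaw of the body relative to
#' travel).
#'
#' @inheritParams hip_tailbase_angle_series
#' @return A [frame_series] in degrees.
#' @export
snout_tailbase_angle_series <- function(rec, signed = FALSE)
  two_marker_series(rec, "ventral", "snout", "tailbase", signed = signed)

#' Left fore-to-hindpaw distance series (ventral plane)
#'
#' Per-frame Euclidean distance in pixels between the left forepaw and the
#' left hindpaw in the bottom-up view.
#'
#' @param rec A cleaned, gap-filled [recording].
#' @return A [frame_series] in pixels (non-negative).
#' @export
left_paw_distance_series <- function(rec) {
  a <- get_track(rec, "ventral", "left_forepaw")
  b <- get_track(rec, "ventral", "left_hindpaw")
  if (any(!a$valid) || any(!b$valid))
    validation_error("paw tracks contain masked samples; run clean_recording() first")
  frame_series(sqrt((a$x - b$x)^2 + (a$y - b$y)^2),
               frame_rate = rec$frame_rate,
               imputed = a$imputed | b$imputed)
}

#' Reduce a frame series to a recording-level scalar
#'
#' @param series A [frame_series].
#' @param stat `"mean"` (default) or `"median"`; imputed frames are
#'   included.
#' @return A single numeric value bounded by the series range.
#' @export
summarize_series <- function(series, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  v <- series$values
  if (length(v) < 1) insufficient_data_error("empty series")
  switch(stat, mean = mean(v), median = stats::median(v))
}

#' Export a frame series as a tidy data frame
#'
#' @param series A [frame_series].
#' @return `data.frame(frame, time_s, value, imputed)`.
#' @export
series_to_df <- function(series) {
  n <- length(series$values)
  data.frame(frame = seq_len(n) - 1L,
             time_s = (seq_len(n) - 1L) / series$frame_rate,
             value = series$values,
             imputed = series$imputed)
}
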