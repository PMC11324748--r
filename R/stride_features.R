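# Stride segmentation: peaks of the anterior-posterior paw coordinate mark
# maximal forward excursion (one stance onset per gait cycle); consecutive
# peaks delimit one stride.

local_maxima <- function(x) {
  s <- sign(diff(x))
  # carry the previous non-zero slope across plateaus
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  filled <- s[nz][cumsum(nz)]
  filled[cumsum(nz) == 0] <- 0
  which(diff(filled) < 0) + 1L
}

peak_prominence <- function(x, peak) {
  h <- x[peak]
  left <- if (peak > 1) x[seq_len(peak - 1)] else numeric(0)
  right <- if (peak < length(x)) x[(peak + 1):length(x)] else numeric(0)
  base_min <- function(v, from_peak_outward) {
    if (length(v) == 0) return(h)  # edge peak: no base on this side
    if (from_peak_outward) v <- rev(v)
    higher <- which(v > h)
    if (length(higher) > 0) v <- v[seq_len(higher[1] - 1)]
    if (length(v) == 0) h else min(v)
  }
  h - max(base_min(left, TRUE), base_min(right, FALSE))
}

#' Detect stride peaks in a paw trajectory
#'
#' Finds local maxima of the anterior-posterior paw coordinate subject to a
#' minimum inter-peak distance and a minimum topographic prominence. The
#' defaults self-tune to the animal's cadence: the distance floor is a
#' quarter of the dominant gait period (from the Welch spectrum, falling
#' back to 3 Hz when no dominant frequency exists) and the prominence floor
#' is a quarter of the signal's interquartile range, which rejects tracking
#' ripple without touching true stride peaks.
#'
#' @param signal A gap-filled [frame_series] (AP paw coordinate, pixels).
#' @param min_distance Minimum frames between peaks; default
#'   `0.25 * frame_rate / f_dom`.
#' @param min_prominence Minimum peak prominence in signal units; default
#'   `0.25 * IQR(values)`.
#' @param f_dom Dominant gait frequency in Hz used for the distance
#'   default; estimated from the signal when `NULL`.
#' @return Integer vector of peak frame indices (1-based, ascending);
#'   possibly empty.
#' @export
detect_stride_peaks <- function(signal, min_distance = NULL,
                                min_prominence = NULL, f_dom = NULL) {
  x <- signal$values
  fs <- signal$frame_rate
  if (is.null(min_distance)) {
    if (is.null(f_dom)) {
      f_dom <- tryCatch(dominant_frequency(welch_psd(signal)),
                        pdssm_error = function(e) 3)
    }
    min_distance <- 0.25 * fs / f_dom
  }
  if (is.null(min_prominence))
    min_prominence <- 0.25 * stats::IQR(x)

  cand <- local_maxima(x)
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(p) peak_prominence(x, p), numeric(1))
  cand <- cand[prom >= min_prominence & prom > 0]
  if (length(cand) <= 1) return(cand)

  # enforce min distance, keeping taller peaks first
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord)
    if (all(abs(kept - p) >= min_distance)) kept <- c(kept, p)
  sort(kept)
}

#' Swing and stance durations within one stride
#'
#' Splits a stride's frames by the sign of the first-difference
#' anterior-posterior velocity: frames where the paw moves in the direction
#' of body advance (against belt drag) are swing, all others -- including
#' zero-velocity frames, tied to ground contact -- are stance. Per-frame
#' sign labels are passed through a running majority filter of
#' `smooth_window` frames, which leaves noise-free signals untouched
#' (including their phase boundaries) but stops tracking jitter from
#' flipping isolated frames of the slow stance drift into spurious swing.
#' The two durations partition the stride period exactly.
#'
#' @param signal A [frame_series] (AP paw coordinate).
#' @param start_frame,end_frame Stride interval, half-open
#'   `[start_frame, end_frame)`, 1-based.
#' @param advance_sign +1 if body advance is toward increasing image x
#'   (default), -1 otherwise; set from the belt direction.
#' @param smooth_window Odd width (frames) of the majority filter on the
#'   velocity-sign labels; 1 disables smoothing.
#' @return Named numeric vector `c(swing_s, stance_s)`.
#' @export
swing_stance_phases <- function(signal, start_frame, end_frame,
                                advance_sign = 1, smooth_window = 5) {
  if (end_frame - start_frame < 2)
    validation_error("degenerate stride: fewer than two frames")
  v <- diff(signal$values[start_frame:end_frame]) * advance_sign
  is_swing <- v > 0
  w <- as.integer(smooth_window)
  if (w > 1 && length(is_swing) > w) {
    if (w %% 2 == 0) w <- w + 1L
    h <- (w - 1L) %/% 2L
    padded <- c(rep(is_swing[1], h), is_swing,
                rep(is_swing[length(is_swing)], h))
    votes <- as.numeric(stats::filter(as.numeric(padded), rep(1, w),
                                      sides = 2))
    is_swing <- votes[(h + 1):(h + length(is_swing))] > w / 2
  }
  fs <- signal$frame_rate
  swing <- sum(is_swing) / fs
  c(swing_s = swing, stance_s = (end_frame - start_frame) / fs - swing)
}

#' Segment a paw trajectory into strides
#'
#' Builds one stride event per consecutive peak pair: period from the peak
#' spacing (stride frequency = 1/T), amplitude as the within-stride range
#' (max - min) of the AP coordinate, and swing/stance durations via
#' [swing_stance_phases()].
#'
#' @param signal A gap-filled [frame_series].
#' @param peaks Peak frame indices from [detect_stride_peaks()] (>= 2).
#' @param paw Paw label stored with the result.
#' @param advance_sign Belt-direction sign, see [swing_stance_phases()].
#' @return An object of class `stride_set`: list with `paw` and `events`,
#'   a data frame with one row per stride (`start_frame`, `end_frame`,
#'   `period_s`, `frequency_hz`, `amplitude`, `swing_s`, `stance_s`).
#' @export
segment_strides <- function(signal, peaks, paw = "left_forepaw",
                            advance_sign = 1) {
  if (length(peaks) < 2)
    pdssm_error("pdssm_insufficient_strides_error", sprintf(
      "%d peak(s) detected; need at least 2 to delimit a stride", length(peaks)))
  peaks <- sort(as.integer(peaks))
  fs <- signal$frame_rate
  k <- length(peaks) - 1
  events <- do.call(rbind, lapply(seq_len(k), function(i) {
    s <- peaks[i]; e <- peaks[i + 1]
    seg <- signal$values[s:(e - 1)]
    ph <- swing_stance_phases(signal, s, e, advance_sign)
    data.frame(start_frame = s, end_frame = e,
               period_s = (e - s) / fs, frequency_hz = fs / (e - s),
               amplitude = max(seg) - min(seg),
               swing_s = ph[["swing_s"]], stance_s = ph[["stance_s"]])
  }))
  structure(list(paw = paw, events = events, frame_rate = fs),
            class = "stride_set")
}

#' Recording-level stride summary
#'
#' Arithmetic means over stride events: frequency (per-event 1/T),
#' amplitude, swing and stance durations.
#'
#' @param strides A `stride_set` from [segment_strides()].
#' @return Named list `mean_frequency_hz`, `mean_amplitude`,
#'   `mean_swing_s`, `mean_stance_s`.
#' @export
stride_summary <- function(strides) {
  ev <- strides$events
  if (is.null(ev) || nrow(ev) == 0)
    pdssm_error("pdssm_insufficient_strides_error", "empty stride set")
  list(mean_frequency_hz = mean(ev$frequency_hz),
       mean_amplitude = mean(ev$amplitude),
       mean_swing_s = mean(ev$swing_s),
       mean_stance_s = mean(ev$stance_s))
}

#' Export strides as a tidy table
#'
#' @param strides A `stride_set`.
#' @param animal_id Optional animal identifier column.
#' @return Data frame with one row per stride event, including onset time
#'   in seconds.
#' @export
strides_to_df <- function(strides, animal_id = NA_character_) {
  ev <- strides$events
  cbind(data.frame(animal = animal_id, paw = strides$paw,
                   start_s = (ev$start_frame - 1) / strides$frame_rate),
        ev)
}
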