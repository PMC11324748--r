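#' Welch power spectral density of a paw trajectory
#'
#' Estimates the one-sided PSD by Welch's method: the signal is split into
#' overlapping segments, each segment is mean-detrended, tapered with a Hann
#' window, and its periodogram computed; the periodograms are averaged.
#' Frequency bins above `fmax` (default 10 Hz, the analysis band for mouse
#' gait at this belt speed) are discarded after estimation.
#'
#' @param signal A gap-filled [frame_series] (no masked samples).
#' @param fmax Upper frequency bound in Hz retained in the spectrum.
#' @param segment_length Samples per Welch segment; default
#'   `min(256, length(signal))`.
#' @param overlap Fractional segment overlap in \[0, 1); default 0.5.
#' @param detrend `"constant"` (subtract segment mean, default) or `"none"`.
#' @return An object of class `power_spectrum` with fields `frequencies`
#'   (Hz, ascending, uniformly spaced), `power` (signal-units^2/Hz,
#'   non-negative), `bin_width` and `fmax_applied`.
#' @export
welch_psd <- function(signal, fmax = 10, segment_length = NULL,
                      overlap = 0.5, detrend = c("constant", "none")) {
  detrend <- match.arg(detrend)
  x <- signal$values
  fs <- signal$frame_rate
  n <- length(x)
  if (anyNA(x)) validation_error("signal contains NA; gap-fill first")
  if (fs <= 2 * fmax)
    pdssm_error("pdssm_aliasing_error", sprintf(
      "frame rate %g too low to resolve %g Hz (need > %g)", fs, fmax, 2 * fmax))
  nseg <- if (is.null(segment_length)) min(256L, n) else as.integer(segment_length)
  if (n < nseg)
    insufficient_data_error(sprintf(
      "signal of %d samples shorter than one Welch segment (%d)", n, nseg))
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)

  # Hann window and its power normalisation (density scaling)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  scale <- 1 / (fs * sum(w^2))

  nfreq <- nseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    if (detrend == "constant") seg <- seg - mean(seg)
    ft <- stats::fft(seg * w)[1:nfreq]
    p <- scale * (Mod(ft)^2)
    # one-sided spectrum: double all bins except DC (and Nyquist if present)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  power <- acc / length(starts)
  freqs <- (seq_len(nfreq) - 1) * fs / nseg
  keep <- freqs <= fmax
  structure(list(frequencies = freqs[keep], power = power[keep],
                 bin_width = fs / nseg, fmax_applied = fmax),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, df = %g Hz, capped at %g Hz\n",
              length(x$frequencies), x$bin_width, x$fmax_applied))
  invisible(x)
}

#' Dominant frequency of a power spectrum
#'
#' Frequency of the maximum-power bin. The 0 Hz bin is excluded so the DC
#' posture offset cannot dominate; ties are broken toward the lowest
#' frequency. Never exceeds the spectrum's frequency cap.
#'
#' @param spectrum A `power_spectrum` from [welch_psd()].
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(spectrum) {
  keep <- spectrum$frequencies > 0
  f <- spectrum$frequencies[keep]
  p <- spectrum$power[keep]
  if (length(p) == 0 || all(p == 0))
    pdssm_error("pdssm_no_dominant_frequency_error",
                "spectrum has no positive-power bin above 0 Hz")
  f[which.max(p)]  # which.max returns the first (lowest-frequency) maximum
}

#' Power at the dominant frequency
#'
#' The PSD value (power density) at the bin selected by
#' [dominant_frequency()].
#'
#' @inheritParams dominant_frequency
#' @return Power in signal-units^2/Hz.
#' @export
dominant_amplitude <- function(spectrum) {
  fd <- dominant_frequency(spectrum)
  spectrum$power[match(fd, spectrum$frequencies)]
}

#' Anterior-posterior paw signal for spectral and stride analysis
#'
#' Extracts the paw's ventral-plane coordinate along the belt axis (image
#' x by default) as a [frame_series].
#'
#' @param rec A cleaned [recording].
#' @param paw `"left_forepaw"` or `"left_hindpaw"`.
#' @param axis `"x"` (belt axis, default) or `"y"`.
#' @return A [frame_series] in pixels.
#' @export
paw_ap_signal <- function(rec, paw = c("left_forepaw", "left_hindpaw"),
                          axis = c("x", "y")) {
  paw <- match.arg(paw)
  axis <- match.arg(axis)
  tr <- get_track(rec, "ventral", paw)
  if (any(!tr$valid))
    validation_error(sprintf("'%s' contains masked samples; run clean_recording() first", paw))
  frame_series(tr[[axis]], frame_rate = rec$frame_rate, imputed = tr$imputed)
}

#' Export a spectrum as a data frame
#'
#' @param spectrum A `power_spectrum`.
#' @return `data.frame(frequency_hz, power)`.
#' @export
spectrum_to_df <- function(spectrum)
  data.frame(frequency_hz = spectrum$frequencies, power = spectrum$power)
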