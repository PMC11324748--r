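# Fixtures built in code: minimal tracks and a hand-assembled two-view
# recording independent of the synthetic generator, so module tests do not
# lean on the code they are meant to validate elsewhere.

mk_track <- function(x, y = rep(0, length(x)), lik = rep(1, length(x)),
                     marker = "tailbase", view = "ventral", fs = 160) {
  marker_track(marker, view, x, y, lik, frame_rate = fs)
}

# recording with constant posture markers and sinusoidal left paws
mk_recording <- function(n = 800, fs = 160, f_paw = 4, amp = 30,
                         hip = c(0, 10), tb_lat = c(10, 10),
                         snout = c(0, 5), tb_ven = c(10, 5),
                         animal_id = "fix_01", condition = "control") {
  t <- (seq_len(n) - 1) / fs
  paw_fore <- 100 + amp / 2 * sin(2 * pi * f_paw * t)
  paw_hind <- 40 + amp / 2 * sin(2 * pi * f_paw * t + pi)
  cv <- function(v) rep(v, n)
  recording(
    animal_id = animal_id, condition = condition, frame_rate = fs,
    tracks = list(
      ventral = list(
        snout = mk_track(cv(snout[1]), cv(snout[2]), marker = "snout"),
        tailbase = mk_track(cv(tb_ven[1]), cv(tb_ven[2])),
        left_forepaw = mk_track(paw_fore, cv(50), marker = "left_forepaw"),
        left_hindpaw = mk_track(paw_hind, cv(52), marker = "left_hindpaw")),
      lateral = list(
        hip = mk_track(cv(hip[1]), cv(hip[2]), marker = "hip", view = "lateral"),
        tailbase = mk_track(cv(tb_lat[1]), cv(tb_lat[2]), view = "lateral"))))
}

# independent spectral oracle: raw DFT periodogram argmax below fmax, DC excluded
dft_dominant_freq <- function(x, fs, fmax = 10) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f > 0 & f <= fmax
  f[keep][which.max(p[keep])]
}

# independent cycle-count oracle: upward mean-crossings
zero_crossing_cycles <- function(x) {
  s <- x > mean(x)
  sum(diff(s) == 1)
}

expect_pdssm_error <- function(expr, class) {
  expect_error(expr, class = class)
}
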