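# Synthetic two-view marker trajectories with known ground truth, used to
# validate every pipeline stage in the absence of deposited video data.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Ground-truth gait parameters for the synthetic generator
#'
#' Defaults describe a healthy mouse walking a 20 cm/s belt filmed at
#' 160 frames/s: stride cadence near 3.5 Hz, ~60 px stride excursion, a
#' 0.40 swing fraction, a shallow hip-tailbase posture angle and small
#' body yaw, with mild tracking noise and a 3% low-likelihood dropout rate.
#'
#' @param stride_freq_fore,stride_freq_hind Stride frequency per paw, Hz.
#' @param stride_amp Peak-to-trough AP paw excursion, pixels.
#' @param swing_fraction Fraction of the cycle spent in swing, in (0, 1).
#' @param phase_offset Fore-to-hind phase offset, radians.
#' @param posture_hip_angle Lateral hip-to-tailbase angle, degrees.
#' @param body_yaw Ventral snout-to-tailbase angle, degrees.
#' @param paw_separation Fore-to-hindpaw baseline distance, pixels.
#' @param noise_sd Gaussian tracking jitter, pixels.
#' @param dropout_rate Fraction of samples given likelihood < 0.25.
#' @param cycle_jitter_sd Relative sd of the instantaneous stride frequency
#'   (stride-interval irregularity).
#' @param duration_s,frame_rate Recording length and sampling rate.
#' @param waveform `"sawtooth"` (fast forward swing, slow backward stance;
#'   duty cycle controllable) or `"sine"` (for spectral tests).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `gait_params` list.
#' @export
gait_params <- function(stride_freq_fore = 3.5, stride_freq_hind = 3.5,
                        stride_amp = 60, swing_fraction = 0.40,
                        phase_offset = pi, posture_hip_angle = 10,
                        body_yaw = 5, paw_separation = 80,
                        noise_sd = 1.5, dropout_rate = 0.03,
                        cycle_jitter_sd = 0.02, duration_s = 4,
                        frame_rate = 160, waveform = c("sawtooth", "sine"),
                        seed = 1L) {
  waveform <- match.arg(waveform)
  p <- list(stride_freq_fore = stride_freq_fore,
            stride_freq_hind = stride_freq_hind,
            stride_amp = stride_amp, swing_fraction = swing_fraction,
            phase_offset = phase_offset,
            posture_hip_angle = posture_hip_angle, body_yaw = body_yaw,
            paw_separation = paw_separation, noise_sd = noise_sd,
            dropout_rate = dropout_rate, cycle_jitter_sd = cycle_jitter_sd,
            duration_s = duration_s, frame_rate = frame_rate,
            waveform = waveform, seed = as.integer(seed))
  validate_gait_params(p)
  structure(p, class = "gait_params")
}

validate_gait_params <- function(p) {
  chk <- function(ok, msg) if (!ok) pdssm_error("pdssm_parameter_error", msg)
  chk(p$frame_rate > 0, "frame_rate must be positive")
  chk(p$stride_freq_fore > 0 && p$stride_freq_fore < p$frame_rate / 2 &&
        p$stride_freq_hind > 0 && p$stride_freq_hind < p$frame_rate / 2,
      "stride frequencies must lie in (0, frame_rate/2)")
  chk(p$swing_fraction > 0 && p$swing_fraction < 1,
      "swing_fraction must lie in (0, 1)")
  chk(p$dropout_rate >= 0 && p$dropout_rate < 1,
      "dropout_rate must lie in [0, 1)")
  chk(p$stride_amp >= 0 && p$noise_sd >= 0 && p$cycle_jitter_sd >= 0,
      "amplitudes and noise parameters must be non-negative")
  chk(p$duration_s > 0, "duration_s must be positive")
  invisible(p)
}

# phase accumulated with slowly varying frequency jitter (AR(1)-smoothed)
jittered_phase <- function(f0, n, fs, jitter_sd) {
  if (jitter_sd > 0) {
    e <- stats::rnorm(n, 0, jitter_sd)
    for (i in 2:n) e[i] <- 0.98 * e[i - 1] + sqrt(1 - 0.98^2) * e[i]
    finst <- f0 * (1 + e)
  } else finst <- rep(f0, n)
  cumsum(2 * pi * finst / fs)
}

# AP paw waveform on phase u in [0,1): swing = fast forward ramp over the
# first `s` of the cycle, stance = slow backward drift at ~belt speed
paw_wave <- function(phase, amp, swing_frac, waveform) {
  if (waveform == "sine") return(amp / 2 * sin(phase))
  u <- (phase / (2 * pi)) %% 1
  ifelse(u < swing_frac,
         -amp / 2 + amp * u / swing_frac,
         amp / 2 - amp * (u - swing_frac) / (1 - swing_frac))
}

likelihoods <- function(n, dropout_rate) {
  drop <- stats::runif(n) < dropout_rate
  lik <- stats::runif(n, 0.6, 1.0)
  lik[drop] <- stats::runif(sum(drop), 0, 0.2499)
  list(likelihood = lik, drop = drop)
}

corrupt <- function(xy, drop) {
  # dropout samples are mis-tracked: displace them far from the truth
  xy[drop] <- xy[drop] + stats::runif(sum(drop), -60, 60)
  xy
}

make_marker <- function(name, view, x, y, params, fs) {
  n <- length(x)
  lk <- likelihoods(n, params$dropout_rate)
  marker_track(name, view,
               x = corrupt(x + stats::rnorm(n, 0, params$noise_sd), lk$drop),
               y = corrupt(y + stats::rnorm(n, 0, params$noise_sd), lk$drop),
               likelihood = lk$likelihood, frame_rate = fs)
}

#' Generate one synthetic two-view recording
#'
#' Builds ventral (snout, tailbase, left paws) and lateral (hip, tailbase)
#' marker tracks: paw AP coordinates follow the configured periodic
#' waveform, posture markers are quasi-static at the configured angles, and
#' every track carries tracking noise plus low-likelihood dropouts whose
#' coordinates are displaced, so the likelihood filter has real work to do.
#' Deterministic given `params$seed`.
#'
#' @param params A [gait_params] object.
#' @param animal_id,condition Metadata stored in the recording.
#' @return A [recording] that passes marker validation.
#' @export
generate_recording <- function(params, animal_id = "sim_01",
                               condition = "control") {
  validate_gait_params(params)
  fs <- params$frame_rate
  n <- round(params$duration_s * fs)
  with_seed(params$seed, {
    ph_fore <- jittered_phase(params$stride_freq_fore, n, fs, params$cycle_jitter_sd)
    ph_hind <- jittered_phase(params$stride_freq_hind, n, fs, params$cycle_jitter_sd) +
      params$phase_offset

    fore_x <- 300 + paw_wave(ph_fore, params$stride_amp, params$swing_fraction,
                             params$waveform)
    hind_x <- 300 - params$paw_separation +
      paw_wave(ph_hind, params$stride_amp, params$swing_fraction, params$waveform)

    yaw <- params$body_yaw * pi / 180
    body_len <- 90
    tb_v <- c(200, 120)
    snout_v <- tb_v + body_len * c(cos(yaw), sin(yaw))

    hip_ang <- params$posture_hip_angle * pi / 180
    hip_len <- 30
    hip_l <- c(250, 140)
    tb_l <- hip_l + hip_len * c(cos(hip_ang), sin(hip_ang))

    cv <- function(v) rep(v, n)
    tracks <- list(
      ventral = list(
        snout = make_marker("snout", "ventral", cv(snout_v[1]), cv(snout_v[2]), params, fs),
        tailbase = make_marker("tailbase", "ventral", cv(tb_v[1]), cv(tb_v[2]), params, fs),
        left_forepaw = make_marker("left_forepaw", "ventral", fore_x, cv(100), params, fs),
        left_hindpaw = make_marker("left_hindpaw", "ventral", hind_x, cv(102), params, fs)),
      lateral = list(
        hip = make_marker("hip", "lateral", cv(hip_l[1]), cv(hip_l[2]), params, fs),
        tailbase = make_marker("tailbase", "lateral", cv(tb_l[1]), cv(tb_l[2]), params, fs)))

    rec <- recording(animal_id = animal_id, condition = condition,
                     tracks = tracks, frame_rate = fs)
    rec$ground_truth <- params  # retained so validation can compare recovery
    rec
  })
}

#' Cohort presets for synthetic studies
#'
#' Each preset is a set of per-animal parameter distributions (mean, sd).
#' The `pd` preset differs from `control` in the directions characteristic
#' of the parkinsonian phenotype: reduced stride amplitude, elevated
#' hip-tailbase posture angle, larger body yaw, slower cadence and larger
#' stride-interval jitter. `pd_dbs` is intermediate, emulating partial
#' rescue under stimulation.
#'
#' @param name `"control"`, `"pd"` or `"pd_dbs"`.
#' @return A `cohort_preset` list: `name` plus `(mean, sd)` pairs per
#'   [gait_params] field that varies across animals.
#' @export
cohort_preset <- function(name = c("control", "pd", "pd_dbs")) {
  name <- match.arg(name)
  base <- list(
    stride_freq = c(3.5, 0.25), stride_amp = c(60, 6),
    swing_fraction = c(0.40, 0.03), posture_hip_angle = c(10, 2.5),
    body_yaw = c(5, 1.5), paw_separation = c(80, 5),
    noise_sd = c(1.5, 0.3), dropout_rate = c(0.03, 0.01),
    cycle_jitter_sd = c(0.02, 0.005))
  pd <- utils::modifyList(base, list(
    stride_freq = c(2.7, 0.35), stride_amp = c(35, 6),
    swing_fraction = c(0.33, 0.04), posture_hip_angle = c(22, 4),
    body_yaw = c(13, 3), cycle_jitter_sd = c(0.09, 0.02),
    dropout_rate = c(0.05, 0.015)))
  pd_dbs <- utils::modifyList(base, list(
    stride_freq = c(3.1, 0.3), stride_amp = c(48, 6),
    swing_fraction = c(0.37, 0.035), posture_hip_angle = c(15, 3),
    body_yaw = c(8, 2), cycle_jitter_sd = c(0.05, 0.01),
    dropout_rate = c(0.04, 0.012)))
  structure(list(name = name,
                 dist = switch(name, control = base, pd = pd, pd_dbs = pd_dbs)),
            class = "cohort_preset")
}

draw_trunc <- function(ms, lo, hi) min(max(stats::rnorm(1, ms[1], ms[2]), lo), hi)

#' Generate a synthetic cohort
#'
#' Draws per-animal gait parameters from a preset's distributions
#' (truncated to valid ranges) using per-animal seeds derived from a single
#' master seed, and generates one recording per animal. Reproducible.
#'
#' @param n Number of animals (>= 1).
#' @param preset A [cohort_preset] or preset name.
#' @param seed Master integer seed.
#' @param duration_s,frame_rate Recording length and sampling rate.
#' @return List of [recording] objects with distinct animal ids and the
#'   preset name as condition.
#' @export
generate_cohort <- function(n, preset = "control", seed = 1L,
                            duration_s = 4, frame_rate = 160) {
  if (is.character(preset)) preset <- cohort_preset(preset)
  if (!inherits(preset, "cohort_preset"))
    pdssm_error("pdssm_parameter_error", "preset must be a cohort_preset or name")
  if (n < 1) pdssm_error("pdssm_parameter_error", "n must be >= 1")
  animal_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  d <- preset$dist
  lapply(seq_len(n), function(i) {
    p <- with_seed(animal_seeds[i], {
      f0 <- draw_trunc(d$stride_freq, 0.5, 9.5)
      gait_params(
        stride_freq_fore = f0,
        stride_freq_hind = min(max(f0 + stats::rnorm(1, 0, 0.05), 0.5), 9.5),
        stride_amp = draw_trunc(d$stride_amp, 5, 200),
        swing_fraction = draw_trunc(d$swing_fraction, 0.05, 0.95),
        phase_offset = stats::runif(1, 0, 2 * pi),
        posture_hip_angle = draw_trunc(d$posture_hip_angle, 0.5, 85),
        body_yaw = draw_trunc(d$body_yaw, 0.5, 85),
        paw_separation = draw_trunc(d$paw_separation, 20, 200),
        noise_sd = draw_trunc(d$noise_sd, 0, 10),
        dropout_rate = draw_trunc(d$dropout_rate, 0, 0.5),
        cycle_jitter_sd = draw_trunc(d$cycle_jitter_sd, 0, 0.5),
        duration_s = duration_s, frame_rate = frame_rate,
        seed = animal_seeds[i])
    })
    generate_recording(p, animal_id = sprintf("%s_%02d", preset$name, i),
                       condition = preset$name)
  })
}

#' Write a recording as DLC-dialect CSV tables
#'
#' @param rec A [recording].
#' @param dir Output directory; files are named
#'   `<animal_id>_ventral.csv` / `<animal_id>_lateral.csv`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_recording_dlc <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ventral = file.path(dir, paste0(rec$animal_id, "_ventral.csv")),
    lateral = file.path(dir, paste0(rec$animal_id, "_lateral.csv")))
  write_dlc_table(rec$tracks$ventral, paths[["ventral"]])
  write_dlc_table(rec$tracks$lateral, paths[["lateral"]])
  invisible(paths)
}
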