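---
title: "Methods: from pose-tracking tables to the PD-SSm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pose-tracking tables to the PD-SSm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdssm)
```

## Overview and assumptions

`pdssm` post-processes markerless tracking output for mice walking a
treadmill at constant belt speed (default 20 cm/s), filmed at a fixed frame
rate (default 160 frames/s) from a ventral and a lateral camera. The
pipeline assumes:

* the tracking table follows the DeepLabCut CSV dialect (three header rows,
  an x/y/likelihood column triple per bodypart, frame index in column 0);
* the image x-axis is parallel to belt travel ("horizontal"); a tilted
  camera can be accommodated upstream by rotating coordinates before input;
* one animal per video, with the required markers per view — ventral:
  snout, tailbase, left forepaw, left hindpaw; lateral: hip, tailbase. The
  left side faces the lateral camera, so only left-paw features are
  defined;
* the time base is frame index / frame rate; no timestamps are read.

## Track cleaning

Samples with likelihood strictly below 0.25 are **masked rather than
deleted**. Deleting rows would break the uniform sampling that the spectral
stage requires; masking and then interpolating on the regular frame grid
preserves it. Masked interior samples are filled by linear interpolation
between the nearest valid neighbours; leading/trailing runs, where a linear
fill is undefined, are extended with the nearest valid value. Filled
samples are flagged `imputed` and the flags propagate into the per-frame
feature series, so downstream consumers can audit how much of a series is
reconstructed. The filter is applied per marker; a frame is never dropped
wholesale because one marker failed.

## Pose features (I–III)

The hip→tailbase (lateral) and snout→tailbase (ventral) angles are measured
against the image x-axis and folded into [0, 90]°: a "deviation from
horizontal" carries no sign convention, and folding makes the measure
invariant to which endpoint is named first. The signed angle in (−90, 90]
is available (`signed = TRUE`) for diagnostics. Feature III is the
per-frame Euclidean distance between the left paws in pixels; no
pixel-to-cm calibration is applied since scoring is calibration-free (both
the controls and the scored animal are measured in the same units).

Each per-frame series is reduced to one scalar per recording by the
arithmetic mean (median available via `summary_stat`), imputed frames
included: a reducer must exist for scoring, and the mean is the least
surprising default for quasi-stationary posture series.

## Spectral features (IV–VII)

The anterior–posterior coordinate of each left paw is analysed with Welch's
method: overlapping segments, per-segment constant detrend, Hann taper,
averaged one-sided periodograms. Parameters (all configurable):

| parameter | default | rationale |
|---|---|---|
| segment length | min(256, n) samples | 1.6 s at 160 fps; 3–8 segments in a 3–5 s recording balances bias and variance |
| overlap | 50 % | standard for Hann tapering |
| detrend | per-segment mean | removes the posture offset drift |
| frequency cap | 10 Hz | mouse stride cadence lies well below it; applied after estimation |

The **dominant frequency** is the argmax bin above 0 Hz — the DC bin is
excluded so a static posture offset cannot win — with ties broken toward
the lowest frequency. Consequently no reported dominant frequency can
exceed 10 Hz. The **dominant amplitude** is the PSD value at that bin
(power density, signal-units²/Hz), not back-converted to signal units. The
analysed signal is the x (belt-axis) coordinate; the axis is configurable.
Signals are not band-pass filtered before analysis.

## Stride features (VIII–XV)

Strides are delimited peak-to-peak on the AP paw coordinate (maximal
anterior excursion, one stance onset per cycle; trough-to-trough available
via configuration). Peak detection uses local maxima subject to

* a minimum inter-peak distance of 0.25 × frame_rate / f_dom frames, with
  f_dom taken from the Welch spectrum (fallback 3 Hz when no dominant
  frequency exists) — self-tuning to the animal's cadence;
* a minimum topographic prominence of 25 % of the signal's interquartile
  range, which rejects tracking ripple without touching genuine stride
  peaks.

Each consecutive peak pair yields one stride event with period T (stride
frequency 1/T) and amplitude max − min of the AP coordinate within the
stride. **Swing vs stance** is decided per frame by the sign of the
first-difference velocity: motion in the direction of body advance
(opposite belt drag; sign configurable) is swing, everything else —
including zero-velocity frames, tied to ground contact — is stance. The
sign labels pass through a 5-frame running majority filter: on noise-free
signals the filter is an identity (including at phase boundaries), but it
stops frame-level tracking jitter from flipping isolated frames of the slow
stance drift into spurious swing, which would otherwise bias the swing
fraction toward 0.5. Swing and stance durations partition T exactly.
Recording-level stride features are arithmetic means over events.

## Control reference and PD-SSm

Per feature, nested central 68/95/99 % bands are estimated from the control
cohort. The default estimator is gaussian, mean ± z·sd with z = 1.000,
1.960, 2.576 — the conventional ±1σ reading of "68 %" (the exact two-sided
68 % multiplier would be 0.994; the difference is far below the
cohort-sampling noise at n = 13). With 13 controls, empirical 99 %
percentiles are essentially order statistics of the extremes, so the
percentile estimator is offered only for large cohorts. Nesting is enforced
by construction.

Scoring is two-sided and inclusive at the bounds: 0 inside the 68 %
interval, 1 between 68 % and 95 %, 2 between 95 % and 99 %, 3 beyond 99 %.
The PD-SSm is the sum over the 15 features, hence 0–45. A feature that
could not be computed (e.g. a paw with fewer than two detected strides)
contributes 0 and is disclosed via `n_scored`, keeping totals comparable
while flagging reduced support. Features are treated independently; no
multivariate covariance is modelled, so correlated features (e.g. the two
paws' cadences) can double-count one underlying deficit — a property
inherited from the score's definition.

## Synthetic gait generator

The generator emulates what the pipeline consumes, with known ground truth:

* paw AP trajectories as a sawtooth-like cycle — fast forward swing over a
  controllable duty fraction, slow backward stance drift — so swing/stance
  ground truth exists; a pure-sine mode serves the spectral tests;
* stride-interval irregularity as AR(1)-smoothed jitter of the
  instantaneous cycle frequency;
* quasi-static posture markers placed at configured hip/yaw angles;
* isotropic gaussian tracking noise, plus low-likelihood dropouts
  (likelihood ~ U(0, 0.25)) whose coordinates are additionally displaced by
  up to ±60 px, so the likelihood filter has real errors to remove;
* valid samples carry likelihood ~ U(0.6, 1).

Cohort presets draw per-animal parameters from truncated normal
distributions using seeds derived from one master seed (fully
reproducible). The `control` preset describes a healthy mouse at the 20
cm/s belt speed: cadence 3.5 ± 0.25 Hz, stride excursion 60 ± 6 px, swing
fraction 0.40 ± 0.03, hip angle 10 ± 2.5°, noise 1.5 px, 3 % dropout —
values a treadmill gait study of healthy C57Bl/6 mice would consider
typical. The `pd` preset shifts the parkinsonian directions: reduced
amplitude (35 px) and cadence (2.7 Hz), elevated hip angle (22°) and yaw,
four-fold stride-interval jitter, more dropout; `pd_dbs` is intermediate,
emulating partial rescue.

**What the generator does not emulate:** paw occlusions correlated with
gait phase, camera distortion, animal drift along the belt, fur/lighting
artefacts, or non-stationary behaviour (stops, rearing). Passing tests on
synthetic cohorts therefore demonstrate the correctness of the computation
and the internal consistency of the pipeline — not the biological validity
of the features on any particular real dataset.

## Numerical choices and degenerate inputs

* Angle of coincident points is an error, not 0.
* Dominance ties break toward the lowest frequency; the all-zero spectrum
  (constant signal) raises a classed error rather than returning 0 Hz.
* A track with fewer than two valid samples cannot be interpolated
  (classed error); a paw with fewer than two stride peaks yields missing
  stride features, not a crash.
* Zero-variance control features raise a degenerate-reference error naming
  the feature.
* A value exactly on a band bound takes the lower score (inclusive
  membership).

## Problem sizes used in validation

The test suite and the reproduction script run on synthetic cohorts sized
to the study design they emulate — 13 control and 7 PD animals, 3–5 s
recordings at 160 frames/s — plus a 10⁴-draw gaussian sample for the
scoring-calibration check; the full suite completes in a few seconds.

## Known limitations

* Only left-side paw features are defined (single lateral camera).
* The swing/stance rule is a kinematic proxy from ventral video; it has no
  access to ground-reaction forces, so brief foot drags during swing are
  classified by velocity direction alone.
* Dominant amplitude is a power density and depends on Welch parameters;
  compare it only across recordings analysed with identical settings.
* The HDF5 variant of the tracking table is not read; convert to CSV
  upstream.
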