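Package: pdssm
Title: Treadmill Gait Analysis and Parkinson's Disease Severity Scoring for Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for markerless pose-tracking tables of
    treadmill-walking mice in the DeepLabCut CSV dialect. Cleans marker
    trajectories by likelihood masking and linear gap interpolation, extracts
    fifteen gait features in three classes (body pose angles, Welch
    power-spectral-density dominant frequency and amplitude of each left paw,
    and per-stride swing/stance/frequency/amplitude from peak-detected stride
    segmentation), and scores each recording against nested 68/95/99%
    confidence bands estimated from a healthy control cohort to yield the
    Parkinson's disease severity score for mice (PD-SSm, 0-45). Includes a
    synthetic gait generator with known ground truth for validation and a
    command-line interface for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
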