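Package: lonewatch
Title: Passive-Sensing Pipeline for Detecting Maternal Social Loneliness from Smartwatch Data
Version: 0.1.0
Authors@R:
    person("Lonewatch", "Developers", email = "lonewatch@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for predicting maternal social
    loneliness from passively sensed smartwatch data. Converts raw wrist
    photoplethysmography (PPG) into cleaned interbeat intervals via
    quality gating, zero-phase bandpass filtering, adaptive-threshold
    peak detection and interval error rejection; computes resting heart
    rate and six short-term heart-rate-variability parameters; derives
    nightly sleep and daily physical-activity features; assembles
    labeled 8-day samples around UCLA loneliness questionnaire
    responses with valid-day filtering and within-sample mean
    imputation; and evaluates decision-tree and gradient-boosting
    classifiers under leave-one-participant-out cross-validation with
    recursive feature elimination on activity features. Includes a
    synthetic-cohort generator with known ground truth so every stage
    is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    quadprog,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
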