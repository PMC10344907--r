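Package: skillcurve
Title: Scoring, Screening and Predictive Modelling for Multi-Session
    Sequence-Tapping Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for keystroke-level motor
    sequence-tapping studies run over multiple sessions. Scores trials by
    counting correct keypresses against a cyclic target pattern, applies
    the qualification/attention/sleep exclusion cascade used in online
    multi-session designs, fits saturating-exponential learning curves
    with a fatigue term, engineers trial- and session-level predictor
    tiers (learning-curve parameters, tapping-consistency dynamics,
    LOWESS profile features, session statistics, micro-online and
    micro-offline gains, raw per-trial performance), and evaluates
    stepped gradient-boosted-tree prediction of future performance and
    learning with train-only standardisation and a single hold-out
    split. Includes classical association analyses (offline-gain t-tests,
    test-retest reliability matrices, retention-decay correlations,
    quantile rank-stability bands) and a keystroke-level synthetic cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
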