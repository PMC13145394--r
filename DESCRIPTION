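Package: affectsense
Title: Passive-Sensing Prediction of Momentary Negative Affect
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting momentary negative affect
    (NA) from passively sensed smartphone and smartwatch data aligned to
    ecological momentary assessment (EMA) prompts. Provides a synthetic
    cohort generator with a known ground-truth mixed model and realistic
    missingness; cleaning and 2-hour block aggregation of heart-rate, step
    and activity streams with proportional-overlap weighting; GPS mobility
    features via movement annotation, density-based clustering of stationary
    points and night-rule home detection; a structural-zero versus
    missing-completely-at-random missingness policy with ordered inclusion
    filters; eleven regression approaches under one fit/predict contract,
    including intercept benchmarks, a mixed-effect random forest and an
    embedding-personalized feedforward network with embedding-only
    fine-tuning; and a leakage-safe evaluation harness with stratified user
    holdout, chronological splits, expanding-window cross-validation and
    in-fold preprocessing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
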