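Package: gapoverlap
Title: Simulation and Analysis of Gap-Overlap Eye-Tracking Studies of
    Attentional Disengagement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the development of attentional disengagement
    with the Gap-Overlap saccade task. Provides a synthetic-data generator for
    accelerated longitudinal cohorts (trial schedules, gaze-sample streams with
    realistic noise, data loss and contaminant trials, and questionnaire
    responses coupled to a latent trait), a preprocessing pipeline from raw
    gaze samples to saccadic reaction times (dispersion-based fixation
    classification, RMS sample-to-sample precision and data-loss metrics, area
    of interest assignment, and a quality filter cascade), per-participant gap
    and facilitation effects, bootstrap Spearman correlations with
    shuffled-age null distributions for mixed longitudinal/cross-sectional
    designs, random-intercept mixed models, paired longitudinal comparisons
    with Holm correction, cross-wave correlation matrices, and questionnaire
    scoring with T-score classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    lme4,
    car,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
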