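Package: psytrs
Title: Reward-Learning, Glutamate and Prediction Markers of Treatment
    Resistance in Early Psychosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the behavioural-computational analysis of
    longitudinal early-psychosis cohorts: a double-update reinforcement
    learning model of an emotion-yoked probabilistic reward task with
    maximum-likelihood fitting and model-based ideal-choice classification,
    an emotional-bias statistic, mixed ANOVAs on learning and bias, quality
    control and group statistics for MRS glutamate (Glu/tCr), Fisher r-to-z
    comparison of group correlations, rule-based treatment-resistance
    labelling (TRRIP-style), and a five-feature logistic model predicting
    treatment resistance at follow-up. Includes a synthetic-cohort generator
    that emulates the study design (15 treatment-resistant vs 35
    treatment-responsive participants, two visits, 60/40 reward
    contingencies) for end-to-end simulation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    dplyr,
    tibble,
    tidyr,
    rlang,
    lhs,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
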