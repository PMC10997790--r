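Package: goseprog
Title: Full-Scale GOSE Outcome Prediction After Traumatic Brain Injury
Version: 0.1.0
Authors@R:
    person("goseprog", "maintainers", email = "goseprog@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating 8-category Glasgow Outcome
    Scale Extended (GOSE) prognostic models for traumatic brain injury from
    the IMPACT admission variables (age, GCS-motor score, pupillary
    reaction, Marshall CT class). Provides a from-scratch proportional-odds
    logistic regression with the Brant test of the parallel-regression
    assumption, a multi-category evaluation suite (accuracy within k
    categories, average balanced accuracy, mean and standard-deviation
    discrepancy, category-proportion discrepancies, dichotomized AUROCs,
    calibration curves), a balanced-undersampling ensemble with median
    probability aggregation, stratified splitting and cross-validation,
    sample-size learning curves, and a synthetic cohort generator with a
    latent proportional-odds outcome so every stage is testable without
    clinical registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    yaml
Config/testthat/edition: 3
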