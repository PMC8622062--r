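Package: hopeval
Title: HOPE Survival Score and External-Validation Toolkit for Hypothermic Cardiac Arrest
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the HOPE (Hypothermia Outcome Prediction after
    Extracorporeal life support) survival probability for hypothermic
    cardiac-arrest patients rewarmed with ECLS, from the six admission
    covariates (age, sex, mechanism of hypothermia, core temperature, serum
    potassium, CPR duration), and provides the full external-validation
    pipeline around it: threshold-based triage diagnostics with Wilson
    confidence intervals, ROC/AUC discrimination with DeLong intervals,
    calibration-in-the-large, and a synthetic-cohort simulator with an
    outcome-dependent retention filter that reproduces the
    publication-bias mechanism by which case-report samples preserve
    discrimination while breaking calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    pROC,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
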