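Package: icpdyn
Title: Dynamic Mortality Prediction from Intracranial and Arterial
    Pressure Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamic 30-day mortality prediction in ICU-monitored
    traumatic brain injury patients from minute-resolution intracranial
    pressure (ICP) and mean arterial pressure (MAP) time series.
    Implements preprocessing of sparse minute-gridded pressure signals
    (extreme-value exclusion, cerebral perfusion pressure derivation),
    rolling-time-window feature engineering over begin/end/trend
    aggregations, a pooled time-window logistic regression with
    recursive feature elimination under stratified patient-level
    cross-validation, time-dependent discrimination and error-rate
    evaluation (AUC, AUPRC, false-positive and false-negative
    proportions at configurable risk thresholds), and a calibrated
    synthetic neuromonitoring cohort simulator for end-to-end testing
    without access-restricted ICU data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
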