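Package: cceann
Title: Curative Care Expenditure Accounting and Neural-Network Sensitivity
    Analysis for Hospital Discharge Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Apportions institution-level curative income and basic
    expenditure allowance onto individual hospital admissions following the
    System of Health Accounts 2011 (SHA2011) sharing-coefficient scheme,
    aggregates curative care expenditure (CCE) along disease, institution and
    age dimensions, fits a single-hidden-layer perceptron regression of
    per-admission hospitalization expenditure on eight patient and encounter
    factors, and ranks cost drivers with Garson connection-weight sensitivity
    analysis averaged over random restarts. Includes a synthetic
    discharge-record generator with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
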