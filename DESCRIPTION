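Package: pvkit
Title: Pharmacovigilance Signal Detection for Spontaneous Reporting Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for disproportionality analysis of spontaneous
    adverse-event reporting data in the FAERS quarterly ASCII dialect:
    case deduplication and primary-suspect extraction, 2x2 contingency
    tables with four signal-detection algorithms (reporting odds ratio,
    proportional reporting ratio, the BCPNN information component, and
    the empirical Bayes geometric mean), designated-medical-event
    screening against an open term-map format, sex- and age-stratified
    subgroup analysis by stratified reporting odds ratios and logistic
    regression, and Weibull time-to-onset modelling with failure-type
    classification. Includes a synthetic spontaneous-report generator
    with planted drug-event associations of known strength so the whole
    pipeline is testable without access to a live database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
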