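Package: pvsignal
Title: Disproportionality Signal Detection and Time-to-Onset Modelling for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance analysis of spontaneous
    reporting system data in the FAERS quarterly-file dialect: ingestion and
    FDA-style deduplication of case reports, drug-event contingency tables at
    the MedDRA preferred-term and system-organ-class levels, four
    disproportionality estimators (reporting odds ratio, proportional
    reporting ratio with Yates-corrected chi-square, Bayesian confidence
    propagation information component, and empirical-Bayes gamma-Poisson
    shrinkage) combined into a six-condition signal rule, Weibull modelling of
    time to onset with failure-type classification, and sex-stratified onset
    comparison. A synthetic-report generator with planted relative-risk
    structure makes every stage testable without access to the real databases.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
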