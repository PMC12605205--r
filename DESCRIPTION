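Package: faerspv
Title: Pharmacovigilance Signal Detection and Risk Modelling for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for spontaneous-report drug-safety analysis in the
    style of FDA Adverse Event Reporting System (FAERS) studies: reading and
    deduplicating FAERS-format quarterly ASCII tables, extracting a drug and
    indication cohort, four-algorithm disproportionality signal detection
    (reporting odds ratio, proportional reporting ratio, Bayesian confidence
    propagation neural network information component, and the DuMouchel
    multi-item gamma Poisson shrinker), Weibull time-to-onset hazard
    classification with Kaplan-Meier stratified comparisons, and a LASSO-Cox
    drug-related-mortality risk score with time-dependent ROC evaluation.
    Includes a synthetic FAERS generator with a planted-truth ledger so every
    stage is verifiable without access to the live database.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    glmnet,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
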