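Package: ipmnaudit
Title: Guideline Rule Engine and Concordance Auditing for Side-Branch IPMN Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A policy-table-driven rule engine for surveillance of side-branch
    intraductal papillary mucinous neoplasms (SB-IPMN) under the Kyoto
    decision framework: detectors for high-risk stigmata and worrisome
    features, recommendation of management action, modality and interval;
    an auditor that classifies actual management as concordant, over- or
    under-surveillance and computes imaging-burden and incidence metrics
    per patient-year; the accompanying cohort statistics (descriptive
    summaries, univariable screen, multivariable logistic regression with
    p < 0.2 selection); and a synthetic longitudinal cohort generator so
    the whole system is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
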