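Package: esbi
Title: Electronic Alcohol Screening and Brief Intervention Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable engine for hospital-outpatient electronic alcohol
    screening and brief intervention (e-SBI). Implements the survey flow
    (paging, a 12-month drinking gate, and interruption/resume via linkage
    identifiers), scoring of the AUDIT, AUDIT-C, Leeds Dependence
    Questionnaire and a trauma history scale, four-way AUDIT-C risk
    classification, personalized feedback (Widmark peak blood alcohol
    concentration, monthly alcohol spend, and guideline/normative
    comparisons with below-guideline suppression), feasibility metrics for
    a recruitment episode (consent, screening mix, completion,
    acceptability, retention), and a seeded synthetic-cohort generator so
    every component is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
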