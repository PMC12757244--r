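Package: faersignal
Title: Pharmacovigilance Signal Detection and Time-to-Onset Analysis for
    FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for case/non-case pharmacovigilance analysis of
    spontaneous adverse-event report databases distributed in the FDA Adverse
    Event Reporting System (FAERS) quarterly ASCII dialect. Provides readers
    and writers for the DEMO/DRUG/REAC/THER/OUTC tables, the CASEID/FDA_DT/
    PRIMARYID deduplication rule, flexible exposure and event classification,
    reporting odds ratios (ROR) with log-Wald confidence intervals and the
    lower-bound signal criterion, stratified disproportionality, complete-case
    logistic regression with crude and adjusted odds ratios and likelihood-ratio
    tests, Weibull time-to-onset analysis with hazard-pattern classification,
    descriptive cohort summaries, and a synthetic report generator with
    recorded ground truth (planted reporting odds ratios, Weibull latencies,
    structured missingness, duplicate report versions) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    withr,
    ggplot2
Config/testthat/edition: 3
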