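Package: bbbclear
Title: Blood-Brain Barrier Integrity and Brain Biomarker Clearance in
    Longitudinal CSF and Blood Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how blood-brain barrier disruption, measured
    as the CSF:blood albumin quotient (Q_A), governs the clearance of brain
    protein biomarkers (S100B, NSE) from cerebrospinal fluid to blood in
    high-frequency neurocritical-care monitoring data.  Provides long-format
    measurement ingestion with unit normalisation, albumin-quotient
    computation and age-banded reference flagging, repeated-measures
    ("momentary") correlation, per-patient lagged cross-correlation with
    pooled peak-lag attribution, marginal generalized-least-squares and
    linear mixed clearance models with ARMA(p,q) within-patient correlation
    (KPSS stationarity screening, AIC structure selection, likelihood-ratio
    and Satterthwaite tests), and a seeded two-compartment synthetic cohort
    generator that emulates the sampling design of a one-week severe
    traumatic brain injury monitoring study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    ggplot2
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
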