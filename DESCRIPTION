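Package: scoremr
Title: Mendelian Randomization with Polygenic Scores for Case-Control Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrumental-variable analysis of a continuous exposure (body mass
    index predicted from a weighted allele score) against a binary disease
    outcome. Provides summary-statistics ingestion and allele harmonization,
    weighted and unweighted genetic-score construction with calibration to
    exposure units, one-sample logistic instrumental-variable analysis with
    stratified and per-study estimates, two-sample Wald-ratio, inverse-variance
    weighted and Egger-regression estimation from summary statistics,
    fixed-effects meta-analysis with Cochran's Q, and a seeded case-control
    genotype simulator that emulates the multi-study design of breast-cancer
    consortium data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
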