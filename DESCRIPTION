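Package: icbtox
Title: Repertoire, Expression and Toxicity Association Analysis for Immune
    Checkpoint Blockade Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing adaptive immune receptor repertoires,
    B cell maturation and clinical toxicity in melanoma cohorts treated with
    immune checkpoint blockade (ICB). Implements depth-matched bootstrap
    rarefaction of clonality metrics (Gini index, clone-size occupancy bands,
    large-clone counts), B cell receptor mutation percentage and IGHC isotype
    usage, median-of-ratios count normalization with geometric-mean signature
    scoring, the lymphocyte-stability (LS) metric with its clinical time
    windows, and genotype/expression association with immune-related adverse
    events (2x2 odds ratios with Fisher exact tests and covariate-adjusted
    logistic regression). A synthetic-cohort generator emulates the
    statistical structure of the access-controlled patient data so every
    stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
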