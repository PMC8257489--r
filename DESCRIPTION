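Package: fptriage
Title: Capture-Rate Calibrated Triage of False Positive Germline Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains, calibrates, selects, and applies per-stratum machine
    learning classifiers that flag likely false positive germline variant
    calls so that orthogonal (Sanger) confirmation can be restricted to
    flagged calls while guaranteeing a target false-positive capture rate.
    Variant calls are labeled true/false positive against a truth set
    restricted to benchmark regions, stratified into six variant-type by
    genotype classes, and scored by classifiers whose decision thresholds
    are calibrated at clinically chosen capture rates. Leave-one-sample-out
    cross-validation, a -2 SD lower-bound acceptance rule, and a modified
    F1 tie-break choose one model per stratum; selected models drive
    per-variant confirm/skip decisions under four clinical risk approaches.
    A synthetic cohort generator makes the full workflow reproducible
    without access to reference sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang (>= 1.0.0),
    generics,
    ggplot2,
    vcfR,
    IRanges,
    GenomicRanges,
    ranger,
    xgboost,
    rpart,
    pROC,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
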