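Package: coretransim
Title: Simulating Core/Transient Species Misclassification Under Imperfect Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based two-habitat metacommunity simulator for studying how
    temporal occupancy performs as a classifier of core versus transient
    community members. Communities on a gridded landscape evolve through death,
    birth, half-normal dispersal, and establishment with external immigration
    from a lognormal regional species pool. A binomial detection overlay turns
    true focal-cell abundances into observed time series, species are classified
    by occupancy thresholds, and confusion-table error rates are analysed as
    functions of detection probability and landscape similarity with OLS and
    logit-link models.
License: MIT
Encoding: UTF-8
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
    utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
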