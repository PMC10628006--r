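Package: chasemetrics
Title: Loss-Chasing Metrics from Account-Based Gambling Transaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs gambling sessions from account-based transaction
    logs using an inter-wager gap rule, computes five per-player behavioral
    metrics of loss-chasing (within-session, across-session and across-days
    rank correlations, regular account depletion and frequent session
    depositing), and compares them across externally assigned gambling-risk
    groups via nonparametric tests, multinomial logistic regression and
    k-means clustering with automated elbow selection. Includes a seeded,
    balance-consistent synthetic cohort generator calibrated to published
    group-level summaries so the full pipeline is testable without access
    to proprietary operator data.
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
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
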