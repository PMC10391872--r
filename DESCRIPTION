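Package: evalqc
Title: Detecting Outlier Evaluators in Multi-Evaluator Measurement Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage quality-control procedure for studies in which many
    evaluators (audiologists, technicians, devices, laboratory batches) obtain
    measurements on study participants. Stage one estimates per-evaluator
    effects on the outcome by cell-means linear regression (single
    measurements) or generalized estimating equations with a robust sandwich
    covariance (correlated repeated measurements, e.g. both ears of one
    participant). Stage two tests each evaluator's effect against the
    (optionally truncated) mean effect with a Wald chi-square contrast,
    calibrates evaluator-specific significance levels to a target power at a
    stated alternative via the noncentral chi-square distribution, estimates
    the false discovery rate among the flagged evaluators, and optionally
    prunes the rejection set based on that estimate. Includes a simulation
    engine emulating audiometric hearing-threshold data for studying the
    procedure's operating characteristics, decision-curve plots of estimated
    FDR against power, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
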