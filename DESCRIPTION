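Package: remdyn
Title: Relational Event Models for Continuous-Time Social Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimate continuous-time relational event models (REMs) from
    timestamped dyadic and group interaction data. Provides risk-set
    construction for undirected (and optionally typed) candidate events,
    splitting of group interactions into evenly spaced dyadic events,
    duration- and group-size-weighted endogenous network statistics
    (inertia, shared partners, and their setting-specific variants) with
    per-time-point standardization, full and ordinal event-history
    likelihoods maximized by Newton-Raphson with analytic derivatives, BIC
    model comparison, a moving-window extension for time-varying
    coefficients, a top-share predictive hit-rate goodness-of-fit metric
    with group-event refinement, and a generative simulator for synthetic
    event histories.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
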