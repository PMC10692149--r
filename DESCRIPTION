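Package: sdtruth
Title: Hierarchical Signal Detection Models of Belief in Political Statements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for model-driven analysis of binary truth judgements of
    political statements. Implements a hierarchical equal-variance signal
    detection theory (SDT) model in which each judgement is a Bernoulli draw
    with probit-linked probability, and both truth discernment (d') and
    response bias (c) carry linear models with crossed random intercepts for
    participants and statements. A companion multivariate zero-one-inflated
    beta (ZOIB) mixed model converts bounded slider ratings into a political
    valence score per statement, from which political concordance is derived.
    Includes a synthetic-study generator with known ground truth,
    registered-style participant inclusion and response-time filters,
    directional hypothesis tests, Savage-Dickey Bayes factors, and
    simulation-based parameter-recovery and power analyses.
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
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics,
    coda,
    rjags
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
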