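Package: motorcomp
Title: Simulation and Analysis of Competitive Motor Decision-Making Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying motor decision-making in a competitive
    reaching game with an asymmetric gain function. Implements the Bayesian
    expected-gain model of aim-point selection under Gaussian motor noise
    (gain function, expected gain, optimal aim point), an alpha-scaled
    virtual opponent whose aim tracks the player's endpoint variability, a
    trial/block/session simulator for individual, competitive, observation
    and threshold protocols, and a synthetic-subject cohort generator with a
    risk-seeking baseline bias, a transient first-block inhibition, and a
    two-slope response to the opponent's relative aim. The analysis layer
    provides risk-sensitivity estimation, relative-aim scatter, split-half
    regression slopes with bootstrap confidence intervals and a permutation
    test, linear versus quadratic model comparison by information criteria,
    paired effect sizes, exact noncentral-t power analysis, and Monte-Carlo
    estimation of the chance of winning a block.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
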