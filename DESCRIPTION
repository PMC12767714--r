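Package: rmnchlca
Title: Multilevel Latent Class Analysis of RMNCH Service Utilization with
    Health-Inequality Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits two-level (women within countries) latent class models to
    binary reproductive, maternal, newborn and child health (RMNCH) service
    indicators by expectation-maximization with multiple restarts, selects the
    number of classes at each level with information criteria and normalized
    entropy, links covariates to class membership at both levels through
    two-step structural logistic regressions, and summarizes country-level
    clustering with the intraclass correlation and median odds ratio. A
    companion suite of health-equity measures (difference and ratio,
    concentration indices, slope and relative indices of inequality,
    population attributable risk and fraction) operates on posterior class
    membership with country-clustered bootstrap confidence intervals. A
    synthetic-data generator emulating the hierarchical survey structure
    supports validation end to end.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
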