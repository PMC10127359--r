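Package: aridtrait
Title: Water-Balance Traits, Binomial Mixed Models and Phylogenetic
    Signal for Desiccation-Resistance Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gravimetric desiccation assays on insects: simulation of
    assay cohorts with known ground truth, derivation of water-balance traits
    (desiccation resistance, water loss rate, water loss tolerance, fractional
    water content) from repeated weighings with interval-censored death times,
    binomial regression of survival proportions by iteratively reweighted least
    squares and by a species random-intercept mixed model integrated with
    adaptive Gauss-Hermite quadrature, and phylogenetic comparative analyses
    (Felsenstein independent contrasts, a contrast-variance signal test with a
    tip-shuffle randomization null, and through-origin contrast correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
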