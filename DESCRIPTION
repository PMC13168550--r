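Package: occuhet
Title: Movement-Driven Detection Heterogeneity in Occupancy Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of avian point-count and passive
    acoustic detection histories under within-territory movement and random
    territory placement, together with covariate-free maximum-likelihood
    occupancy estimators (zero-inflated binomial, zero-inflated
    beta-binomial, and Royle-Nichols), exact Monte Carlo tests for
    site-level detection heterogeneity and model goodness of fit, and an
    experiment harness quantifying occupancy-estimation bias as a function
    of the number of visits per site.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
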