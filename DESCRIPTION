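Package: lekdyn
Title: Open-Population N-Mixture Models for Lek Count Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits dynamic (open-population) N-mixture models to repeated counts
    of unmarked animals at fixed survey sites, in the style used for lek counts
    of prairie grouse. Latent site abundance evolves through binomial apparent
    survival and Poisson recruitment (constant or autoregressive), observed
    through binomial detection; the likelihood is evaluated by a truncated
    forward recursion. Includes maximum-likelihood fitting with Wald inference,
    a staged AIC model-building workflow for weather and grazing covariates,
    empirical-Bayes smoothing of annual abundance with a pre/post-drought
    analysis-of-variance contrast, and a seeded synthetic lek-count generator
    that emulates a 12-year, 49-lek survey design with a severe-drought year.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
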