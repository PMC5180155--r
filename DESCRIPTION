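Package: defrisk
Title: Phylogenetic Comparative Analysis of Chemical Defence and Extinction Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether a binary chemical antipredator defence
    predicts contemporary extinction risk on a time-calibrated phylogeny.
    Implements IUCN Red List threat and status codings, phylogenetic logistic
    regression and Poisson generalized estimating equations, a Bayesian
    ordinal threshold (liability) model with a phylogenetic random effect,
    four-state correlated and directional models of joint trait evolution with
    likelihood-ratio tests (Pagel's test), terminal-branch-age contrasts, and
    birth-death simulations of future lineage fates with a closed-form
    extinction-probability oracle. Includes a synthetic-data generator for
    trees, jointly evolving binary traits, ordinal statuses from a latent
    liability, and Brownian covariates, so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Rcpp,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
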