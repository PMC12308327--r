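Package: dielmk
Title: Constrained Mk Models for the Coevolution of Anti-Predator
    Coloration and Diel Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the joint evolution of a binary
    anti-predator coloration character (cryptic vs conspicuous) and a
    four-level diel-activity character (diurnal, nocturnal, day-and-night
    active, crepuscular) on a time-calibrated phylogeny. Enumerates the
    112 constrained eight-state Mk models in which colour transitions are
    restricted to chosen diel states and diel transitions follow chosen
    connectivity graphs within each colour, forbidding simultaneous
    changes in both traits. Fits each model by maximum likelihood with a
    compiled pruning algorithm, ranks models by AIC and Akaike weights,
    reconstructs marginal ancestral states, samples stochastic character
    maps by uniformization to count realized transitions, and simulates
    matched synthetic datasets (Yule trees plus exact event-time character
    histories) so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
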