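Package: gridpath
Title: Hippocampal Spatial-Cognition Modelling: Stripe-Cell Attractor Path
    Integration, Grid-Cell Assembly and Multi-Scale Position Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a hippocampus-inspired spatial-cognition stack for mobile
    agents: head-direction cells encode speed and heading, one-dimensional
    stripe-cell continuous attractor networks integrate velocity into periodic
    phase codes, three stripe plates 60 degrees apart assemble hexagonal
    grid-cell firing, boundary cells memorise grid activity at arena walls and
    inject it back to cancel accumulated drift, and a multi-scale
    maximum-likelihood decoder reads position out of nested grid modules into a
    place-cell response. Includes a synthetic random-roam trajectory generator,
    noisy dead-reckoning baselines, experiment drivers reproducing stripe
    formation, phase-displacement calibration, boundary-correction and
    decoding-accuracy studies, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
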