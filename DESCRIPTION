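Package: coroflow
Title: Point-Cloud Surrogate Modelling of Coronary Bypass Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Generates idealized stenosed coronary-aortic vessel trees with
    optional bypass grafts, solves steady blood flow on them with a
    Poiseuille hydraulic-network model, and trains a dual-input point-cloud
    neural network that predicts interior velocity and pressure fields from
    wall geometry alone. Includes range-normalized and relative error
    metrics per anatomical region, fractional flow reserve and graft-flow
    clinical indices, Pearson and Bland-Altman method agreement, vorticity
    estimation on scattered points, and training-set-size sweeps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
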