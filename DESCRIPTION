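Package: romkin
Title: Reduced-Order Mass-Action Models of Amyloid Aggregation with
    Physics-Informed Parameter Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and inverse modelling of amyloid-beta aggregation
    kinetics with a family of eight reduced-order mass-action models, in
    which ranges of oligomer sizes are pooled into species bins connected by
    reversible condensation steps. Rate constants are estimated by a
    physics-informed neural network (a small per-experiment multilayer
    perceptron trained on a joint data-misfit and ODE-residual loss, with
    the kinetic parameters shared across experiments as a global fit), or by
    a Levenberg-Marquardt least-squares baseline on integrated trajectories.
    Includes profile-likelihood confidence intervals for fitted rates, a
    synthetic multi-experiment data generator, and an automatic
    reaction-order-reduction workflow that searches the lattice of model
    granularities and selects the coarsest model the data support.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
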