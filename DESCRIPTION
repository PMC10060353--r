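Package: crowddiff
Title: Diffusivity Inference for Interacting Particle Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of per-particle isotropic diffusion coefficients from
    discretely observed trajectories of interacting stochastic differential
    equation systems. Implements a higher-order Gaussian transition-density
    approximation whose covariance incorporates the drift Jacobian, the
    resulting Gamma conjugate posterior on the precision, maximum-likelihood
    estimators, and the naive mean-square-displacement baseline. Includes a
    Brownian-dynamics simulator for attractive-repulsive (Morse-type)
    interacting cell populations with reflecting boundaries, and an
    evaluation harness comparing the two estimators across population
    densities and observation frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
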