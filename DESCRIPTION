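Package: ddmlcs
Title: Drift-Diffusion Decision Parameters and Latent Change Score Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation, quality control, and estimation pipeline linking
    decision-making computations to attention problems in longitudinal
    two-timepoint cohorts. Provides a Wiener first-passage-time density and
    trial simulator for the drift-diffusion model, closed-form EZ-diffusion
    estimation, hierarchical Bayesian estimation of subject-level parameters
    in randomized batches with Gelman-Rubin screening and posterior
    predictive checks, and multigroup univariate and bivariate latent change
    score structural equation models estimated by full-information maximum
    likelihood with chi-square difference tests of sex-equality constraints.
    A synthetic-data module emulates stop-signal-task go-trial sessions and
    parent-rated attention problems with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
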