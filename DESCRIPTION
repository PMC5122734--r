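Package: driftage
Title: Hierarchical Bayesian Diffusion Modelling of Two-Choice Reading Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits hierarchical Bayesian drift-diffusion models to two-alternative
    forced-choice response-time data from single-word reading tasks, with age-group
    level parameters for non-decision time, boundary separation and drift rate.
    Provides the Wiener first-passage-time likelihood (small-time and large-time
    series), trial-level simulation, outlier preprocessing, maximum-a-posteriori
    initialisation, adaptive Metropolis-within-Gibbs sampling, Gelman-Rubin
    convergence diagnostics, posterior-predictive quantile checks, posterior
    exceedance probabilities for group comparisons, and a synthetic-cohort
    generator emulating a three-group, four-task reading study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
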