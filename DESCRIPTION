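Package: driftlearn
Title: Hierarchical Drift-Diffusion Modelling and Random-Forest Analysis of Rule-Hierarchy Learning Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for two-choice decision
    experiments that cross an external difficulty factor (rule hierarchy,
    three levels) with an intrinsic learning factor (block, five levels).
    Provides a synthetic-data generator built on a forward drift-diffusion
    simulation, a Wiener first-passage-time likelihood, hierarchical
    Bayesian estimation by adaptive random-walk Metropolis-Hastings with
    Gelman-Rubin diagnostics, highest-density intervals and posterior
    predictive checks, a four-model comparison via AIC, BIC and
    Pareto-smoothed importance-sampling LOO, repeated-measures ANOVA with
    Greenhouse-Geisser correction, and a leakage-safe random-forest
    importance analysis with participant-grouped cross-validation and
    out-of-bag permutation importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    car,
    ranger,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
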