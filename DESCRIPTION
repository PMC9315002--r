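Package: shellevo
Title: Eggshell Stiffness and the Comparative Analysis of Nest Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a dimensionless eggshell stiffness (the C number) from
    egg geometry with an axisymmetric thin-shell finite-element compression
    model, and relates it to nest characteristics with phylogenetic
    comparative methods: phylogenetic generalized least squares with Pagel's
    lambda and AICc-based grouping selection, Pagel's dependent/independent
    correlated-evolution model for two binary traits with MCMC and
    stepping-stone Bayes factors, Brownian-motion ancestral state
    reconstruction, and quantile-regression trends of stiffness against node
    depth. Includes seeded generators for trees, trait histories, nest
    categories and egg geometries so the whole pipeline is testable on
    synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Matrix,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    splines,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools
Config/testthat/edition: 3
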