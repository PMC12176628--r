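Package: tundiv
Title: Diversity Change Analysis for Hierarchical Tundra Vegetation Resurveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing plant diversity change in hierarchically
    structured vegetation resurvey data (plots nested in subsites nested in
    study areas), as collected by long-term Arctic monitoring networks.
    Harmonizes percent-cover, point-frame and cover-class surveys to relative
    cover, computes plot-level richness and Pielou evenness, partitions
    temporal turnover into replacement and nestedness (Jaccard family) or
    balanced-variation and abundance-gradient (Bray-Curtis family) components,
    classifies species trajectories (lost, gained, persisting), fits Bayesian
    hierarchical regressions of diversity metrics and their change against
    climatic and biotic drivers with negative-binomial, beta and
    zero-one-inflated-beta likelihoods, tests subsite-level homogenization with
    principal coordinates analysis and multivariate dispersion, runs seeded
    species removal/addition null models, and simulates hierarchical synthetic
    survey and climate data so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vegan,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr
Config/testthat/edition: 3
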