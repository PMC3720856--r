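Package: elevgrad
Title: Elevational Gradient Analysis of Plant Diversity, Composition and
    Biomass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing vegetation change along elevational
    gradients sampled with nested circular plots. Implements Fisher's
    log-series alpha diversity with additive partitioning of plot (alpha)
    and among-plot (beta) diversity, above-ground biomass estimation from
    stem tables via moist-forest allometry with wood-density fallback
    rules, information-theoretic trend modelling (marginality-respecting
    model enumeration, Akaike weights, model-averaged variable importance,
    Mitchell-Olds and Shaw extremum tests), model-based analysis of
    community composition using per-species negative-binomial generalized
    linear models with a PIT residual bootstrap for multivariate analysis
    of deviance, and community phylogenetic structure (mean phylogenetic
    distance, net relatedness index) under the independent-swap null
    model. A synthetic-data generator emulating a stationed nested-plot
    sampling design supports end-to-end testing and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
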