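Package: srmnet
Title: Bayesian Social Relations Models for Multiplex Household Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how material wealth patterns relational
    wealth in small communities. Builds dyadic covariates from raw field
    tables (wealth inventories, pedigrees, GPS coordinates), fits a
    generalized social relations model with stochastic block effects to
    directed binary network layers via Hamiltonian Monte Carlo, handles
    double-sampled name-generator reports through a latent-network
    measurement model (false positives and recall estimated per question),
    and summarizes posteriors as standardized effects, reciprocity
    correlations, and block offset/contrast tables. Includes a synthetic
    community generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    geosphere,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
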