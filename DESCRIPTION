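Package: stringchem
Title: String Chemistry Networks and Constraint-Based Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building complete "chemical universes" of string
    metabolites linked by pairwise condensation and splitting reactions,
    running flux balance analysis on them, pruning them to minimal networks
    that produce a chosen biomass from chosen nutrients, and analyzing
    ensembles of pruned networks (composition similarity, size scans,
    bipartite degree and flux distributions). Universes are defined by an
    alphabet of monomers and a maximum string length; networks export to
    CSV/TSV stoichiometric matrices, JSON, and SBML Level 3 with flux bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
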