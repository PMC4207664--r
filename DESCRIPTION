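Package: vcqtl
Title: Mapping QTL that Control Trait Variances and Covariance Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide mapping of variance-controlling QTL (genetic
    canalization) and of QTL altering multi-trait covariance structure
    (genetic constraint and genotype-by-environment interaction) in
    biparental recombinant inbred line populations. Provides per-marker
    Brown-Forsythe scans with genome-wide permutation significance,
    decomposition of marker-associated variance into mean- and
    variance-difference components, G-matrix comparisons (trace-form Box's
    M, the angle between leading eigenvectors, and the Krzanowski common
    subspace index), mixed-model analysis of heterogeneous inbred family
    experiments including delta-Ct expression responses, and a
    threshold/sigmoid flowering-time simulator for recombinant inbred
    designs across contrasting environments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
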