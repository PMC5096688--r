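Package: propagon
Title: Nucleated-Polymerization Dynamics and R0 Inference for Yeast Prion
    Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Models the propagation of amyloid aggregates (prions) in
    dividing budding yeast cells with the nucleated polymerization model:
    soluble protein is synthesized, converted onto fiber ends, fibers are
    fragmented by chaperones into new heritable templates (propagons), and
    everything is diluted by cell growth.  Provides the closed moment
    system and the full size-resolved ODEs, closed-form steady states, the
    basic reproductive number R0 of an aggregate and its inference from
    measured steady-state soluble fractions, inversion for the
    fragmentation rate, bootstrap confidence intervals and strain
    comparisons, an exact event-driven stochastic simulator of aggregates
    in a cell lineage (including guanidine-curing and recovery protocols
    with per-cell propagon counts), and a synthetic-data generator for a
    six-strain panel with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
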