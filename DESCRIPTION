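Package: rdnaevol
Title: Phylogenetic Dynamics of Ribosomal DNA Clusters on Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-phylogenetic toolkit for the evolution of ribosomal
    DNA (rDNA) clusters across a genus-level karyotype dataset. Fits
    all-rates-different continuous-time Markov models to three-state
    chromosomal characters (cluster absent, pericentromeric, distal) by
    maximum likelihood with a pruning-algorithm core, computes marginal
    ancestral-state probabilities with threshold-based state calls, derives
    insertion and deletion events along branches, tests correlated evolution
    of centromere/cluster binary trait pairs with the dependent-versus-
    independent likelihood-ratio test (chi-square, df = 4), and summarises
    the co-occurrence of chromosomal breakpoints with clusters and
    centromeres. Includes seeded simulators for trees and discrete
    characters and a packaged study fixture so every stage runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
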