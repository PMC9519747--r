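Package: orselect
Title: Pseudotime Phase Analysis of Olfactory Receptor Selection in Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the onset of odorant receptor (OR) expression
    along the olfactory sensory neuron lineage in single-cell RNA-seq data.
    Orders cells along pseudotime, ranks OR genes within each cell into a
    winner and runners-up, calls silent/multigenic/monogenic expression
    states, counts active OR gene clusters and chromosomes per cell, tests
    whether co-expressed ORs co-locate in genomic clusters with a
    fixed-margin (curveball) permutation null, screens transcription factors
    and chromatin remodelers for differential expression at phase
    transitions, and scans enhancer sequences for degenerate (IUPAC)
    consensus motifs with mismatches. Ships a negative-binomial synthetic
    data generator that emulates the seven-stage neuronal lineage so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
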