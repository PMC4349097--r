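Package: gcstar
Title: Equilibrium GC Content Under CpG Hypermutability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of lineage-specific, neighbour-dependent nucleotide
    substitution rates from three-species alignment windows by composite maximum
    likelihood, and downstream analysis of the equilibrium GC content they imply.
    The model distinguishes the six reverse-complement-symmetric nucleotide
    exchanges plus a separate CpG->CpA/TpG deamination channel, does not assume
    stationarity, and accounts for multiple hits. The package computes two
    equilibrium GC estimates (with and without CpG hypermutability, the latter by
    a dinucleotide cluster approximation), summarises per-CpG bisulfite read
    counts into window methylation levels and frequencies, derives per-window
    composition and recombination statistics, and runs the regression stage:
    partial correlations from multiple linear regression, Pearson matrices, and
    principal component regression with a variance decomposition. A
    synthetic-data generator produces alignments, methylation tables and
    recombination maps with tunable coupling between methylation and CpG
    hypermutability so the whole pipeline is testable without genome-scale data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
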