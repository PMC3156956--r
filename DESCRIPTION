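Package: tfbm
Title: Breakpoint Graphs and the Turnover Fragile Breakage Model of Genome
    Rearrangement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying breakpoint reuse in circular genomes under
    the random (RBM), fragile (FBM), and turnover fragile (TFBM) breakage
    models of chromosome evolution.  Provides signed gene-order genomes and
    2-break (DCJ) operations, breakpoint graphs with their cycle
    decomposition and the b - c rearrangement distance, simulation of
    2-break scenarios along phylogenetic trees with fragile-site turnover,
    inter- and intra-breakpoint reuse statistics together with their
    breakpoint-graph lower bounds, sampling of shortest 2-break scenarios,
    and the multispecies breakpoint-reuse curve R(l) with its closed-form
    TFBM prediction and parameter estimation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
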