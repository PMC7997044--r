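Package: multicd
Title: Multi-Scale Chromatin Domain Inference from Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers chromatin domains (sub-TADs, TADs, meta-TADs and A/B
    compartments) from intra-chromosomal Hi-C contact matrices within a single
    statistical framework.  A Gaussian polymer-network model maps
    Knight-Ruiz-balanced contact frequencies to pairwise positional
    correlations; a group-model likelihood with a penalty on the generalized
    number of domains is then minimized by simulated annealing, yielding a
    family of domain partitions indexed by a single resolution parameter.
    Includes secondary (compartment) inference on band-masked or residual
    correlation matrices, domain-comparison statistics (binary-matrix
    similarity, normalized mutual information, nestedness), boundary-signal
    cross-correlation, and generators that simulate correlation matrices and
    Hi-C counts from the model for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
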