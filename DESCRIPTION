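Package: sigrekin
Title: Sigma-Factor Regulon Inference from Expression Kinetics and Promoter Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether an alternative sigma factor drives, or
    represses, the expression of its chromatin-immunoprecipitation-associated
    target genes. Implements preprocessing of single-replicate expression time
    courses (exponentiation from log2, Savitzky-Golay smoothing, uniform
    resampling), three-way profile classification against regulator profiles,
    an ODE kinetic model of regulator-driven transcription fitted by
    multi-restart simulated annealing whose signed weight distinguishes
    activation from repression, bipartite -35/-10 promoter motif construction
    and scanning with exact position-weight-matrix p-values over variable
    spacers, hypergeometric functional enrichment, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    Biostrings,
    rtracklayer,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
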