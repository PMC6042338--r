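Package: pausefold
Title: DNA Secondary-Structure Free Energy and RNA Polymerase II
    Promoter-Proximal Pausing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools linking single-stranded DNA secondary-structure free
    energy to RNA polymerase II promoter-proximal pausing. Provides a
    nearest-neighbor minimum-free-energy folding engine for DNA (with an
    exhaustive-enumeration oracle and optional G-quadruplex scoring),
    sliding-window genome-wide and TSS-proximal free-energy scans on the
    non-template strand, calling of highly stable structure sites,
    permutation (shuffle) enrichment against Pol II ChIP-seq features,
    traveling-ratio pausing classification, an annotation-free pause-site
    caller built on GRO/NET/mNET-seq signals with a power-law coverage
    null and FDR control, anchored free-energy and coverage profile
    matrices, mutant cumulative delta-delta-G analysis with robust
    regression, and a synthetic-data generator with a truth manifest so
    the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    MASS,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
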