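Package: satrep
Type: Package
Title: Satellite Repeat Binding, Divergence and Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the regulatory state of satellite DNA
    arrays from ChIP-seq and CUT&RUN data: classification of repeat copies
    by factor binding, iterative majority-consensus reconstruction and
    per-copy percent divergence by global alignment, a randomization-based
    peak-feature overlap test with add-one empirical p-values and
    observed/expected ratios, trimmed-mean coverage profiles with
    per-feature signal statistics, occupancy subsets with repeat-class
    length fractions, and TPM / delta-delta-Ct expression utilities.
    Includes a deterministic synthetic genome generator (satellite arrays,
    peaks, coverage tracks) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
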