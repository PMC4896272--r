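Package: bsdbh
Title: Bisulfite Read Alignment and Methylation Calling with a Succinct
    de Bruijn Hash Index
Version: 1.0.0
Authors@R: person("bsdbh", "developers", role = c("aut", "cre"),
    email = "bsdbh@example.org")
Description: Aligns directional bisulfite-treated sequencing reads with a
    seed-and-extend strategy built on a bisulfite-aware, Hamming-aware de
    Bruijn hash function, and reconstructs per-cytosine methylation levels
    with memory-compressed counters. The index stores the reference text
    plus a fingerprint-to-positions table over the hashed text; candidate
    placements for a read are generated by enumerating the 2k-radius
    Hamming ball around the seed fingerprint, so C-to-T (and G-to-A)
    bisulfite mismatches carry no alignment penalty. The methylation
    caller marks genomic cytosines in a rank-supported bit-vector, keeps
    strand-specific conversion counts in block-compressed capacity-growing
    arrays, emits Bismark-cov/BED/EPP-style annotations (optionally
    gzipped), and computes target-enrichment statistics from BED intervals.
    A directional BS-seq simulator and evaluation harness are included.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
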