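Package: srnasig
Title: Small RNA Biogenesis Signature Survey
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Survey pipeline for small-RNA sequencing alignments: detection of
    Dicer duplex pairs (2-nt 3' overhangs) and the percent-Dicer-pairs
    statistic, piRNA Ping Pong (10-nt 5' overlap) and Zucchini phasing
    (head-to-tail 1U) signature histograms with z-scores, coverage-based
    annotation of small-RNA-expressing loci with merge-gap/RPM threshold
    sweeps, per-locus read-size profiling and classification, and locus
    expression matrices with normalization, log2 fold changes and PCA.
    Includes a synthetic small-RNA alignment generator with ground-truth
    labels so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
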