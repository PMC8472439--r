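Package: cnvbatch
Title: Batch-Based Copy Number Variant Calling from Exome Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diagnostic copy number variant (CNV) detection from exome
    capture read depth. Samples sequenced together in a batch serve as
    each other's reference: per-target read counts of a test sample are
    compared with an aggregated reference set under a beta-binomial
    observed-fraction model, and copy states are segmented along the
    target lattice with a Viterbi decoder. Downstream stages merge
    fragmented calls, annotate cytogenetic bands, gene and exon overlap,
    microarray and MLPA probe detectability, chromosome-terminus
    proximity, and batch and database frequencies, filter calls against
    clinical gene panels, classify them with a transparent rule cascade,
    estimate mosaic fractions from depth ratios, and summarise cohort
    diagnostic yield. A synthetic-data module generates batches with
    known truth so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
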