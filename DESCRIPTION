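Package: fusionDriveR
Title: Prioritization of Gene Fusions by Deep Scoring of Fused Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs all candidate chimeric proteins implied by a pair of
    genomic breakpoints, given a genome (FASTA) and an Ensembl-style gene
    annotation (GTF), scores each amino-acid sequence with a convolutional plus
    bidirectional-LSTM classifier, aggregates per-fusion scores by maximum into
    an oncogenic probability, and emits a ranked, flag-annotated report.
    Includes a retraining mode that fits a fresh model from user-labeled
    fusions, and a deterministic synthetic-fixture generator (mini-genomes,
    breakpoint sets with oracle proteins, planted-motif labeled datasets) so
    the whole workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    pROC,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
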