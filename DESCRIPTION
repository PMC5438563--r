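Package: medipcpg
Title: Window-Based MeDIP-Seq Methylome Analysis and Normalized CpG
    Content Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to link historic DNA methylation, measured as normalized
    CpG dinucleotide content (CpG observed/expected), with current
    methylation measured by MeDIP sequencing. Provides genomic region
    extraction from FASTA/GFF3 annotation, per-region normalized CpG
    content, Gaussian-mixture bimodality testing with a parametric
    bootstrap likelihood-ratio test, 500-bp window quantification of
    MeDIP fragments in RPKM, negative-binomial exact tests for
    sex-differential methylation with FDR control, resampling and
    permutation tests for CpG depletion of differentially methylated
    genes and for methylated-repeat proximity, and a synthetic-genome
    simulator with a ground-truth ledger for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
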