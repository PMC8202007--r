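Package: mirFFL
Title: miRNA Differential Expression, Expression-Pattern Grading, and
    miRNA-TF-Gene Feed-Forward-Loop Networks for Sex-Disparate
    Hepatocarcinogenesis Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the six-group (sex x {normal, peri-tumor, tumor})
    pooled-library miRNA sequencing design: TMM/TPM normalization,
    no-replicate conditional exact tests with Benjamini-Hochberg control,
    W/P/T expression-pattern grading into HCC- and Ras-related categories,
    miRNA-TF-gene three-node feed-forward-loop network construction with
    hub extraction, genomic imprinted-region localization statistics for
    the Dlk1-Dio3 cluster, hypergeometric over-representation of predicted
    targets, and delta-delta-Ct qPCR validation. A seeded synthetic-data
    generator plants ground-truth differential miRNAs, expression
    patterns, loci and feed-forward loops so that every stage of the
    pipeline has a recoverable answer key.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    S4Vectors,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    rtracklayer,
    fgsea,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
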