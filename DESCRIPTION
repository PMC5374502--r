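Package: scmge
Title: Single-Cell RNA-seq Analysis of Embryonic MGE and MGE-like Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a complete single-cell RNA-seq
    analysis pipeline for characterizing embryonic medial ganglionic
    eminence (MGE) cells and embryonic-stem-cell-derived MGE-like cells:
    per-cell quality-control gating on mapped reads, mitochondrial read
    fraction and gene-detection fraction; nRPKM, molecule-count and
    log2(x+1) normalizations; variance-stabilized PCA with selection of
    genes associated with the leading principal components by moderated
    linear models; hierarchical sub-population clustering; Mann-Whitney
    differential expression with a floored-median log2 fold-change;
    prevalence-rule derivation of cell-type markers and a >=4-marker
    rule-based cell classifier with conflict handling; supervised
    two-signature classification; cross-system fold-change concordance;
    and single-cell qPCR delta-Ct/Z-score analysis. A negative-binomial
    synthetic-data generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    BiocGenerics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'celltype.R'
    'diffexp.R'
    'io.R'
    'preprocess.R'
    'qpcr.R'
    'reduce.R'
    'report.R'
    'scmge-package.R'
    'simulate.R'
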