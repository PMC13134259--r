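Package: screlev
Title: Cell-Type Relevance Scoring of Disease Gene Sets in Single-Cell
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes curated disease gene sets to preferentially
    expressing cell types in single-cell RNA-seq data. Provides per-gene
    cell-type specificity screening (Kruskal-Wallis with
    Benjamini-Hochberg correction), Monte-Carlo disease-relevance scoring
    of cells and cell types against expression- and gene-length-matched
    control gene sets with empirical p-values and z-scores, a
    permutation-based within-type heterogeneity test, driver-gene ranking
    by correlation with per-cell disease scores, temporal classification
    of genes across ordered developmental stages, and cross-organ top-K
    overlap prioritization. Ships a negative-binomial synthetic-data
    generator with planted disease programs and controllable gene-length
    confounding so the whole pipeline is testable without external
    downloads. Includes a curated gene set for congenital anomalies of
    the kidney and urinary tract (CAKUT).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
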