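Package: GeneSetInvariance
Title: Gene-Set Invariance Analysis for Bulk and Single-Cell Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether a focal gene set (for example, curated oncogenes)
    behaves differently from size-matched random gene sets in bulk expression
    data. Implements pairwise sample statistics (Pearson and Spearman
    correlation, rank-binned mutual information with Doane's rule, and
    expression noise as the squared coefficient of variation), a size-matched
    resampling null with empirical percentiles, distribution fitting with AIC
    model selection for low-expression filtering, PCA embeddings with
    between-condition distances, neighbor-joining sample trees, hierarchical
    clustering with separation scoring, interaction-network degree analytics
    with discrete power-law fitting, and per-cluster Wilcoxon differential
    expression for single-cell data. Includes synthetic-data generators with
    planted, recoverable structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    ape,
    igraph,
    fitdistrplus,
    mclust,
    pracma,
    withr,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, SingleCell, Network, StatisticalMethod
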