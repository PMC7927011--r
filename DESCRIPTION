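Package: rggc
Title: Regularized Gaussian Graphical Clustering of Single-Cell RNA-Seq Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Parameter-free clustering of single-cell RNA-seq count matrices
    with a ridge-regularized self-representation (regularized Gaussian
    graphical) model. Each cell is regressed on all other cells with an L2
    penalty; the closed-form solution of the regularized Gram inverse yields a
    high-order partial-correlation adjacency matrix between cells, which is
    partitioned by Louvain modularity maximization so the number of clusters
    is determined automatically. Includes the fixed preprocessing chain
    (log2(x+1), quantile normalization, per-cell z-score), NMI and adjusted
    Rand index validation, a splatter-style gamma-Poisson count simulator with
    group differential-expression factors and logistic dropout, t-SNE
    visualization of the cell-cell similarity matrix, and readers/writers for
    MatrixMarket and dense count formats.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    optparse
Config/testthat/edition: 3
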