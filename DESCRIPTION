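Package: hci
Title: High-Order Correlation Integration for Clustering RNA-seq Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clusters cells or samples from single-cell or bulk expression
    matrices by augmenting each expression view with its first- and
    second-order Pearson sample-correlation matrices, fusing all views
    through an adaptively weighted joint factorization into a global
    low-dimensional sample-pattern matrix, clustering that pattern with
    K-means, estimating the number of clusters from the flattening of the
    within/between distance ratio (RDC) curve, and ranking differential
    features by the coefficient of variation of their factor loadings.
    Includes loaders for dense and Matrix Market sparse expression formats,
    a ground-truth synthetic data generator for single- and multi-view
    benchmarks, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
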