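Package: pcphc
Title: Correlation-Proximity Hierarchical Clustering and Order-Preserving
    Pattern Mining for Gene Expression Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines order-preserving biclusters (GL-PCPHC patterns) from
    real-valued gene expression matrices. Genes are clustered by
    average-linkage agglomeration on a Pearson-correlation proximity
    matrix; dendrogram clusters seed a Seed-Augment growth procedure that
    alternates column and row expansion, under order-violation and
    row-support thresholds, until each seed reaches a maximal pattern of
    rows sharing a common linear ordering of column values. Includes TSV
    expression-matrix input/output, log-ratio transforms, a synthetic
    planted-pattern generator, and planted-bicluster recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
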