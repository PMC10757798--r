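Package: dualica
Title: Dual Independent Component Analysis for Interacting Gene-Condition Modules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts "interacting modules" -- paired sets of genes and
    experimental conditions with coordinated, statistically significant
    dysregulation -- from a genes x conditions matrix of log-fold-changes.
    Two independent component analyses are run, one on the matrix and one on
    its transpose; signed gene and condition clusters are trimmed from the
    tails of each component using the D'Agostino omnibus K-squared normality
    test; component counts are chosen by knee detection on a K-squared scree;
    gene-IC x condition-IC associations are quantified by an outer-product
    statistic, equivalently by coefficients of a melted linear regression,
    with Wald tests, Benjamini-Hochberg correction and Z-score filtering.
    Includes Fisher's exact gene-set enrichment against GMT collections and a
    synthetic planted-module generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ica,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
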