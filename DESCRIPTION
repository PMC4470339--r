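Package: meristemr
Title: Consensus Clustering and Differential Expression for Developmental
    Time-Course RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of bulk RNA-seq developmental time courses
    such as shoot apical meristem stage series: median-of-ratios size-factor
    normalization of total gene read counts, negative-binomial differential
    expression between consecutive stages with Benjamini-Hochberg FDR
    control, two-tier consensus clustering of relative expression profiles
    (k-means ensembles, co-occurrence consensus distances, complete-linkage
    trees and an adaptive dynamic tree cut with a minimum cluster size),
    classification of transition-point expression patterns, cross-experiment
    replication similarity scores, ddCt qPCR quantification, and a
    negative-binomial count simulator with planted profile archetypes that
    gives every pipeline stage a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    mclust,
    stats,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
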