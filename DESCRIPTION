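Package: repometa
Title: Stage-Specific Drug Repositioning from Paired Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for expression-based
    drug repositioning in staged cancers. From paired tumor/normal
    log2-expression matrices it derives up- and downregulated gene signatures
    with a paired moderated-t test, restricts them to clique-percolation
    communities of a protein-protein interaction network, performs
    hypergeometric over-representation analysis against GMT gene-set
    collections, combines per-batch drug enrichment scores on the Fisher-z
    scale with fixed- or random-effects meta-analysis selected by a
    heterogeneity test (Q, I-squared, DerSimonian-Laird tau-squared), and
    ranks and compares candidate drug lists via the Jaccard index with
    mapping to community target genes. A synthetic-data module generates
    every input with the statistical structure the analysis assumes, so the
    whole workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    metafor,
    jsonlite
Config/testthat/edition: 3
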