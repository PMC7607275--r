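Package: circnet
Title: Differential Expression and ceRNA Network Analysis for circRNA
    Profiling Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reproducible pipeline for two-group circRNA microarray
    studies: quantile normalization and fold-change/p-value calling of
    differentially expressed circRNAs (Welch, pooled and empirical-Bayes
    moderated t variants), relative quantification of qRT-PCR validation
    assays by the 2^-ddCt method, gene-set over-representation with
    one-sided hypergeometric p-values and enrichment factors, and
    construction of a tripartite circRNA-miRNA-mRNA competing endogenous
    RNA (ceRNA) network in which candidate pairs are screened by a
    shared-miRNA hypergeometric test.  Includes seeded synthetic-data
    generators that plant known fold changes, enriched terms and ceRNA
    pairs so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
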