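Package: rnaiqc
Title: Error-Rate Auditing for Multi-Reagent RNAi Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditing false-negative and false-positive rates in
    cell-based RNAi high-throughput screens that carry multiple independent
    knockdown reagents per gene.  Provides per-plate Z-score normalization of
    raw plate readings, cross-screen phenotype-profile clustering (Pearson
    correlation, average linkage) with consensus screen signatures,
    concordance classification of multi-reagent genes and reagent-level
    false-negative rate estimation, gene-level hit categorization with
    transcriptome (FPKM) expression filtering, a closed-form and Monte-Carlo
    m-of-k binomial model of hit-disambiguation rules, and a synthetic-data
    generator that emulates 384-well screening plates with an empty
    perimeter, reagent inefficacy and off-target activity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
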