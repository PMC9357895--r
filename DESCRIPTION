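Package: stemtrace
Title: Time-Course Proteomics Analysis of Stem Cell Differentiation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for label-free proteomics time courses of
    directed stem-cell differentiation: preprocessing (master-protein
    filtering, missing-value replacement, per-sample median normalization),
    a day-specificity z-score statistic with threshold selection, k-means
    clustering of combined-replicate temporal profiles with replicate
    composition diagnostics, empirical-Bayes moderated differential
    abundance between adjacent days, hypergeometric over-representation of
    annotation sets, and reference-proteome comparison by Pearson
    correlation with leave-one-protein-out influence analysis. Includes a
    synthetic LFQ data generator with planted ground truth so every stage
    is verifiable without the original raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
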