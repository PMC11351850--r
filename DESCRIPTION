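Package: dielortho
Title: Cross-Species Day-Night Expression Comparison and Ortholog Sign-Flip
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ortholog-anchored pipeline for comparing day-night (diel)
    bulk RNA-seq expression between two related species with opposite
    activity niches. Provides negative-binomial differential expression
    with an exact conditional test and a Wald GLM test, TMM and
    median-of-ratios scaling, reciprocal-best-hit orthology over protein
    sequences with Smith-Waterman scoring, collapse of per-species results
    onto reference-genome orthologs, classification of cross-species
    expression patterns including fold-change sign flips and
    diel-coincidence, GO over-representation, weighted co-expression
    networks (topological overlap, module eigengenes, module-trait
    correlation), alignment-based conservation profiling with
    conserved-block detection and focal-pair mutation mapping, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
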