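Package: regscore
Title: Transcription Factor Gene Scores, Confounder Diagnostics and
    Expression Modeling from ChIP-seq and Open Chromatin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes gene-level transcription factor (TF) scores from TF
    ChIP-seq peaks or from biophysical motif affinities evaluated in open
    chromatin (DNase1-seq) peaks, under nine scoring variants that differ in
    how peak score, peak length, peak count and accessibility signal are
    aggregated with an exponential distance decay around each gene's most 5'
    transcription start site. Fits sparse elastic-net models of gene
    expression with nested Monte-Carlo cross-validation, and provides
    per-gene permutation nulls, pairwise and confounder correlation
    diagnostics, precision-recall evaluation of inferred regulators against a
    gold standard, and a fully synthetic fixture generator with controllable
    confounder structure for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    generics,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
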