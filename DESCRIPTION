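Package: reosig
Title: Relative Expression Ordering Signatures Robust to RNA Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based analysis of within-sample relative expression
    orderings (REOs) of gene pairs, designed for expression data from
    formalin-fixed paraffin-embedded (FFPE) tissue where absolute
    measurements are distorted by partial RNA degradation. Quantifies
    the consistency of gene-pair orderings between paired fresh-frozen
    and FFPE profiles, mines highly stable REOs across accumulated
    normal cohorts, selects reversal-gene-pair signatures between two
    phenotypes by a two-threshold rule ranked on mean absolute rank
    differences, classifies samples by majority vote, and provides a
    paired Rank Product differential-expression stage with
    permutation-based false discovery estimates. Includes a seeded
    synthetic-data generator emulating paired FF/FFPE cohorts with
    gene-specific, tissue-independent degradation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
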