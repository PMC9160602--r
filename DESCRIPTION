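Package: mirdcor
Title: Differential Correlation Analysis of Sperm Small-RNA-Seq miRNA Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting miRNA pairs whose co-expression reverses sign
    between two phenotype groups in small-RNA sequencing data, as applied to
    bovine sperm samples from high- and low-fertility bulls. Implements
    counts-per-million normalization and annotation collapsing of
    sequence-level (isomiR) count tables, expression-level filtering,
    within-group Spearman correlation with exact permutation p-values at small
    sample sizes, an interaction linear model testing for group-specific
    slopes, Benjamini-Hochberg false discovery rate control, and
    classification of differentially correlated pairs. Also provides
    isomiR-level proportion profiling with consensus-sequence flagging, a
    per-isomiR differential t-test with within-annotation correction,
    shared-target set logic for validated miRNA-gene interaction tables, and a
    Gaussian-copula negative-binomial count simulator with planted correlation
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
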