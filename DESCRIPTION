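Package: oxytime
Title: Time-Course Analysis of the Yeast Hypoxic Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying time-dependent gene expression in short
    RNA-seq time courses such as the switch of Saccharomyces cerevisiae from
    aerobic to hypoxic growth. Implements count preprocessing (total-count
    normalization, flooring, fold-change gating), an exhaustive permutation
    test on the lag-1 autocorrelation of each gene's expression series
    (AutoCor), a quadratic-versus-intercept negative-binomial likelihood-ratio
    test with pooled-dispersion estimation, Benjamini-Hochberg significance
    calling and gene-set arithmetic, global-structure analyses (principal
    components, sample distances, UPGMA clustering with uncentered
    correlation), environmental stress response (ESR) overlap, and a
    negative-binomial synthetic time-course generator with a power/false
    discovery evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
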