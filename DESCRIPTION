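Package: pathcord
Title: Cross-Platform Pathway Concordance Analysis for Two-Class
    Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parametric gene set enrichment analysis for two-class
    (tumor versus normal) expression matrices and cross-platform
    concordance of the results. Implements interquartile-range gene
    filtering, probe-to-gene collapse by maximal variability,
    pathway-size pruning, pooled-variance per-gene t-statistics, the
    sum-of-t over square-root-of-set-size enrichment score with normal
    or label-permutation set P-values, and classification of pathways
    and genes into cross-dataset concordance categories. Also provides
    the quantitative validation toolkit used alongside such screens:
    standard-curve qPCR quantification, normalization to endogenous
    controls, percent-of-methylated-reference (PMR) computation with
    methylation calling against a normal panel, and rank-based
    association tests between expression and clinicopathological
    covariates. A synthetic-data generator emulates two partially
    overlapping array platforms with planted pathway-level shifts so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
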