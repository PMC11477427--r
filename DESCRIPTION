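Package: cnarisk
Title: Prognostic Risk-Group Models from Discretized Copy Number Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A systematic pipeline for building prognostic risk-group models
    from GISTIC-thresholded somatic copy number alterations (CNAs). Reads
    gene-by-sample matrices of integer threshold calls in {-2,...,+2},
    derives four binary alteration modes (soft/deep x deletion/amplification),
    screens each recurrent gene region for survival association with a
    permutation-calibrated log-rank test suited to heavily unbalanced carrier
    groups plus a univariate Cox log hazard ratio, and assigns patients to
    high/low/no-risk groups by coefficient sums under three algorithms
    (single-data, MaxSum, Combinations), yielding eight candidate models per
    cohort. Includes Kaplan-Meier and multi-group log-rank evaluation, model
    ranking and selection, cofactor stratification and multivariate Cox
    independence analysis, and a synthetic-cohort generator with planted
    prognostic alterations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
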