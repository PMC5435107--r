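Package: selsum
Title: Polygenic Positive Selection Scans with SUMSTAT Gene Set Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pathways under polygenic positive selection from
    branch-site likelihood-ratio test results. Per-gene log-likelihood
    ratios (delta-lnL) on ancestral phylogenetic branches are reconciled
    across replicate optimizer runs, clamped at zero, fourth-root
    transformed, and aggregated per gene set with the SUMSTAT statistic.
    Significance is assessed against an empirical null of random same-size
    gene sets built by sequential Monte-Carlo sampling, with a top-gene
    removal robustness pass, Storey q-values, iterative pruning of
    overlapping significant sets, and a permutation-based empirical false
    discovery rate. A synthetic-data generator with zero-inflated
    chi-square scores and overlapping set structure supports calibration
    and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
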