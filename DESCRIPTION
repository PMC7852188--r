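Package: robustclust
Title: Subsampling-Based Cluster Robustness Scoring and Parameter Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the robustness of clustering results by repeated
    clustering of random cell subsamples. Pairwise co-clustering frequencies
    across subsampled runs define a consensus distance on which per-cell
    silhouette scores are computed and aggregated into per-cluster robustness
    scores. Bootstrap (BCa) confidence intervals on the median per-cluster
    score across a grid of clustering-parameter values drive a decision rule
    that selects a near-optimal parameter value: the one yielding the most
    clusters while keeping the median score at or above the highest CI lower
    bound. Ships a built-in graph-based clustering backend (library-size
    normalisation, highly variable genes, PCA, kNN graph, Leiden community
    detection) and a plug-in contract for arbitrary user backends, plus Dice
    coefficient comparison of partitionings, 10x-style Matrix Market readers,
    a negative-binomial ground-truth simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
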