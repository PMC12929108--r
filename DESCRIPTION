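Package: dfcstates
Title: Dynamic Functional Connectivity State Analysis for ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity (dFC) analysis
    for region-of-interest (ROI) time series: windowed Pearson correlation
    with Fisher z transformation and dFC variability maps, recurring
    connectivity-state identification by Manhattan-distance K-means with
    elbow model selection, per-subject temporal state metrics (fractional
    windows, mean dwell time, transitions), sparsity-thresholded binary
    graph metrics (efficiency, clustering, degree, betweenness,
    small-worldness) aggregated over a sparsity sweep, and covariate-
    adjusted permutation inference with false-discovery-rate and
    network-based-statistic corrections. Includes a Markov-switching
    multivariate-normal cohort simulator with known ground truth for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
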