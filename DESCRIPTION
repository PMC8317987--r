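Package: graphmarker
Title: Graph-Theoretic Connectome Biomarkers with Elastic-Net Subset
    Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classification analysis of resting-state functional
    connectomes built on local graph-theory features. Computes
    Fisher-z-transformed Pearson connectivity matrices from parcel time
    series, thresholds them over a proportional-density grid and extracts
    density-averaged binary graph metrics (degree, clustering,
    betweenness, local efficiency), selects features with an elastic net
    and a hybrid optimal-subset extension (Enet-subset), and evaluates a
    linear support-vector-machine classifier under a repeated stratified
    train/test protocol with permutation-test significance, node-wise
    rank-sum statistics under false-discovery-rate control, and
    selection-frequency reporting. Includes a synthetic two-group cohort
    generator with covariance-level group effects for end-to-end testing
    and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
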