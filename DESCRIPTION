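Package: pcrfed
Title: Personalized Contrastive-Regularized Federated Learning for Binary
    Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale simulator for personalized federated learning on
    multi-site binary medical-image segmentation. Implements a configurable
    encoder-bridge-decoder (U-Net) segmentation network with manual
    backpropagation, Dice plus binary cross-entropy supervised training, a
    weighted model-contrastive regularizer on pooled bridge representations,
    shared/personalized parameter partitioning, and sample-size-weighted
    server aggregation (FedAvg). Ships a synthetic non-IID multi-site data
    generator (intensity shift and quantity skew), FedAvg and local-only
    baselines, hyperparameter sweeps, and tidy result tables with ggplot2
    visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    RNifti
Config/testthat/edition: 3
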