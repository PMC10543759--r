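Package: mdalink
Title: Microbe-Disease Association Prediction with Graph Attention
    Autoencoders and Positive-Unlabeled Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microbe-disease associations from a sparse bipartite
    association network. Computes Gaussian association-profile kernel
    similarity on each side of the network and fuses it with optional
    functional similarity, learns 64-dimensional node embeddings with a
    graph attention autoencoder, mines reliable negative pairs from the
    unlabeled pool with a spy-based positive-unlabeled learning algorithm
    (K-means spy selection plus a gradient-boosted scorer), and classifies
    concatenated pair embeddings with a deep neural network. Ships three
    five-fold cross-validation regimes (held-out diseases, microbes, or
    pairs), AUC/AUPR metrics, a PU-learning ablation, per-disease candidate
    ranking, and a synthetic low-rank bipartite data generator for
    download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
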