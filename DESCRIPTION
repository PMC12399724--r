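Package: harclust
Title: Two-Phase Feature Extraction and Clustering for Wearable-Sensor Activity Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unsupervised discovery of human activities in
    multichannel wearable-sensor streams. A supervised spatio-temporal
    feature extractor (convolutional, recurrent, or hybrid
    convolutional-LSTM networks, trained with a built-in backpropagation
    engine) compresses fixed-length sensor windows into latent features,
    which are then clustered with K-Means under a Student-t soft
    assignment or refined with deep embedded clustering (KL-divergence
    against a sharpened target distribution). Includes a labeled
    stream simulator with semi-Markov activity bouts and cross-fade
    transitions, MobiAct-dialect CSV and UCI-HAR raw-signal readers,
    MinMax scaling, sliding-window segmentation, SMOTE rebalancing,
    NMI/ARI/mapped-accuracy evaluation, and a kNN-graph/minimum-spanning-tree
    export for inspecting transitional overlap between activity clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
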