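# harclust

Two-phase feature extraction and clustering for wearable-sensor human
activity recognition (HAR) streams.

Wearable devices emit multichannel inertial time series (accelerometer,
gyroscope, orientation) in which activities — walking, standing, sitting,
falling — must often be discovered without labels. Clustering raw sensor
windows works poorly: the data are high-dimensional, noisy, and activities
flow into each other through brief unlabeled transitions. `harclust` is for
researchers and engineers who want a tested, self-contained R
implementation of the two-phase answer to this problem:

1. **Phase 1 — supervised spatio-temporal feature extraction.** A neural
   encoder (2-D CNN, MLP autoencoder, conv-front-ended stacked LSTM
   autoencoder, hybrid 1-D conv + LSTM, time-distributed conv, or a
   tri-headed multi-resolution conv/BiLSTM with kernel widths 5/7/11) is
   trained to classify fixed-length sensor windows with categorical
   cross-entropy; its latent layer becomes the window representation.
2. **Phase 2 — unsupervised clustering.** K-Means (k-means++ seeding, Lloyd
   iterations, best of `n_init` restarts) over the latent features, scored
   with a Student-t soft assignment

   q_ij = (1 + ||z_i − μ_j||²/α)^(−(α+1)/2) / Σ_j' (…),   α = 1,

   or deep embedded clustering (DEC): a 500–500–2000→10 stacked
   autoencoder pretrained by reconstruction, centroids initialized by
   K-Means, then encoder and centroids refined jointly by minimizing
   KL(P‖Q) against the sharpened target p_ij ∝ q_ij²/f_j, stopping at
   20,000 iterations or when fewer than 0.1% of hard labels change
   between target updates.

Partitions are scored with NMI, ARI and optimal-mapping accuracy
(Hungarian matching). A kNN-graph → minimum-spanning-tree export (GraphML)
lets you inspect how transitional windows sit between their flanking
activities. A labeled stream simulator (semi-Markov activity bouts,
per-activity quasi-periodic signatures, linear cross-fade transitions,
additive noise) makes the whole pipeline testable without downloading any
benchmark dataset. The neural layers, backpropagation and Adam are
implemented in the package and gradient-checked against finite differences
in the test suite.

## Worked example

The default pipeline simulates 6 activities at 200 Hz for 120 s, cuts
1-second windows at 50% overlap, MinMax-scales to [0, 1], trains the
hybrid conv+LSTM extractor for 20 epochs on a stratified 64/16/20 split,
clusters all windows with K-Means (k = 6), and exports the spanning tree:

```r
library(harclust)
cfg <- default_pipeline_config(seed = 1)
res <- run_pipeline(cfg)
#> [harclust] simulate: 6 activities, 120s @ 200 Hz
#> [harclust] preprocess: windows of 200 @ overlap 0.50
#> [harclust] train: hybrid_conv_lstm, 20 epochs
#> [harclust] cluster: kmeans, k = 6
#> [harclust] evaluate: NMI 0.819  ARI 0.768  acc 0.828
print(res$report)
#> <eval_report> n=239  k_true=6  k_pred=6
#>   NMI 0.8194 | ARI 0.7681 | mapped accuracy 0.8285
res$classification_accuracy
#> [1] 0.8571429
```

Reading the numbers: the 239 windows are grouped into 6 clusters whose
agreement with the simulated ground truth is NMI 0.82 / ARI 0.77, and
82.9% of windows are correct under the best one-to-one cluster-to-class
mapping; the classification head reaches 85.7% on the held-out test split.
The run directory (`res$run_dir`) holds the stream CSV, the extractor
checkpoint (JSON), latent features, soft/hard assignments, the evaluation
report, the GraphML tree and a checksummed manifest that makes the run
re-describable. Training on all windows rather than the 64% split, as in
whole-dataset clustering protocols, raises agreement to NMI ≈ 0.91
(see the acceptance script below, which does exactly that).

Lower-level entry points: `simulate_stream()` / `write_stream_csv()` /
`read_mobiact_csv()` / `read_uci_har_dir()`, `fit_scaler()` /
`segment_windows()` / `smote_upsample()`, `build_spec()` /
`train_supervised()` / `train_autoencoder()` / `encode()` / `classify()`,
`kmeans_fit()` / `soft_assign()` / `target_distribution()` /
`kl_divergence()` / `dec_fit()`, `nmi()` / `ari()` / `cluster_accuracy()`,
`knn_graph()` / `mst()` / `export_graph()`. A thin CLI wrapper lives at
`inst/cli/har.R` (`Rscript har.R run config.yaml`).

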