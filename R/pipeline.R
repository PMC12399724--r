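# End-to-end orchestration: simulate -> preprocess -> train -> extract ->
# cluster -> evaluate -> visualize, driven by a single validated config.

PIPELINE_SCHEMA <- list(
  seed = NULL, out_dir = NULL, run_id = NULL,
  simulate = c("k", "n_channels", "rate_hz", "total_duration_s",
               "transition_len_s", "noise_sd", "transition_label",
               "profile_seed"),
  preprocess = c("window_len", "overlap", "range", "smote", "smote_k",
                 "fit_on"),
  extractor = c("family", "latent_dim", "epochs", "overrides"),
  cluster = c("method", "k", "alpha", "n_init", "pretrain_epochs",
              "update_interval", "tol", "max_iter"),
  evaluate = c("enabled"),
  viz = c("enabled", "k")
)

#' Default pipeline configuration
#'
#' Six simulated activities at 200 Hz for 120 s, 1-second windows at 50%
#' overlap scaled to `[0, 1]`, the hybrid conv+LSTM extractor, and K-Means
#' with Student-t soft assignment.
#'
#' @param seed Global seed for every stage.
#' @param out_dir Artifact directory root.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = tempfile("harclust-run-")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    run_id = sprintf("run-%d", as.integer(seed)),
    simulate = list(
      k = 6L, n_channels = 9L, rate_hz = 200, total_duration_s = 120,
      transition_len_s = 0.25, noise_sd = 0.1, transition_label = "incoming",
      profile_seed = 7L
    ),
    preprocess = list(
      window_len = 200L, overlap = 0.5, range = c(0, 1),
      smote = "off", smote_k = 5L, fit_on = "train"
    ),
    extractor = list(
      family = "hybrid_conv_lstm", latent_dim = 32L, epochs = 20L,
      overrides = list()
    ),
    cluster = list(method = "kmeans", k = 6L, alpha = 1, n_init = 10L),
    evaluate = list(enabled = TRUE),
    viz = list(enabled = TRUE, k = 10L)
  )
}

#' Validate a pipeline configuration against the schema
#'
#' Unknown keys (top level or within a stage block) are rejected by name
#' before any stage runs.
#'
#' @param config Nested list (or path to a YAML file).
#' @return The validated (and YAML-loaded) configuration, invisibly usable.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_bad_arg("config must be a list or a YAML file path")
  unknown_top <- setdiff(names(config), names(PIPELINE_SCHEMA))
  if (length(unknown_top) > 0L)
    stop_bad_arg("unknown config key(s): %s", paste(unknown_top, collapse = ", "))
  for (blk in names(PIPELINE_SCHEMA)) {
    allowed <- PIPELINE_SCHEMA[[blk]]
    if (is.null(allowed) || is.null(config[[blk]])) next
    unknown <- setdiff(names(config[[blk]]), allowed)
    if (length(unknown) > 0L)
      stop_bad_arg("unknown config key(s) in `%s`: %s", blk,
                   paste(unknown, collapse = ", "))
  }
  defaults <- default_pipeline_config()
  for (blk in c("simulate", "preprocess", "extractor", "cluster", "evaluate", "viz")) {
    merged <- defaults[[blk]]
    merged[names(config[[blk]])] <- config[[blk]]
    config[[blk]] <- merged
  }
  config$seed <- as.integer(config$seed %||% defaults$seed)
  config$out_dir <- config$out_dir %||% defaults$out_dir
  config$run_id <- config$run_id %||% sprintf("run-%d", config$seed)
  config
}

# stratified 64/16/20 train/val/test split over windows
split_windows <- function(labels, seed) {
  with_seed(seed, {
    split <- character(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      n <- length(idx)
      if (n == 1L) {
        split[idx] <- "train"
        next
      }
      n_train <- max(1L, round(0.64 * n))
      n_val <- round(0.16 * n)
      while (n_train + n_val >= n && n_val > 0L) n_val <- n_val - 1L
      while (n_train + n_val >= n && n_train > 1L) n_train <- n_train - 1L
      split[idx[seq_len(n_train)]] <- "train"
      if (n_val > 0L) split[idx[n_train + seq_len(n_val)]] <- "val"
      split[idx[(n_train + n_val + 1L):n]] <- "test"
    }
    split
  })
}

# rescale a window tensor with per-channel min/max statistics
scale_tensor <- function(tensor, ch_min, ch_max, range = c(0, 1)) {
  lo <- range[1L]; hi <- range[2L]
  for (c in seq_len(dim(tensor)[3L])) {
    rng <- ch_max[c] - ch_min[c]
    tensor[, , c] <- if (rng > 0)
      lo + (tensor[, , c] - ch_min[c]) * (hi - lo) / rng
    else lo
  }
  tensor
}

subset_windows <- function(ws, idx) {
  window_set(ws$tensor[idx, , , drop = FALSE], ws$window_labels[idx],
             window_len = ws$window_len, step = ws$step,
             label_names = ws$label_names, channel_names = ws$channel_names,
             provenance = ws$provenance)
}

#' Run the full two-phase clustering pipeline
#'
#' Executes simulate -> preprocess (scale, segment, optional SMOTE) ->
#' supervised extractor training -> latent extraction -> clustering ->
#' evaluation -> tree export, persisting every intermediate artifact with a
#' checksummed manifest so a run is fully re-describable.
#'
#' @param config Configuration list or YAML path; see
#'   [default_pipeline_config()] and [validate_config()].
#' @param verbose Log stage progress to stderr.
#' @return List with `report` (an `eval_report`), `classification_accuracy`
#'   (test split), `result` (the `cluster_result`), `run_dir`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), verbose = TRUE) {
  config <- validate_config(config)
  run_dir <- file.path(config$out_dir, config$run_id)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[harclust] ", fmt), ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  artifacts <- character(0)

  # -- simulate ---------------------------------------------------------------
  sim <- config$simulate
  stream <- stage("simulate", {
    log_stage("simulate: %d activities, %gs @ %g Hz", sim$k,
              sim$total_duration_s, sim$rate_hz)
    profiles <- make_default_profiles(sim$k, sim$n_channels, seed = sim$profile_seed)
    spec <- stream_spec(
      profiles, rate_hz = sim$rate_hz, transition_len_s = sim$transition_len_s,
      noise_sd = sim$noise_sd, total_duration_s = sim$total_duration_s,
      transition_label = sim$transition_label, seed = config$seed
    )
    simulate_stream(spec)
  })
  stream_csv <- file.path(run_dir, "stream.csv")
  write_stream_csv(stream, stream_csv)
  artifacts <- c(artifacts, stream_csv)

  # -- preprocess -------------------------------------------------------------
  pp <- config$preprocess
  ws_all <- stage("preprocess", {
    log_stage("preprocess: windows of %d @ overlap %.2f", pp$window_len, pp$overlap)
    segment_windows(stream, pp$window_len, pp$overlap)
  })
  split <- split_windows(ws_all$window_labels, seed = config$seed + 1L)
  train_idx <- which(split == "train")
  val_idx <- which(split == "val")
  test_idx <- which(split == "test")
  fit_idx <- if (identical(pp$fit_on, "all")) seq_along(split) else train_idx
  ch_min <- apply(ws_all$tensor[fit_idx, , , drop = FALSE], 3L, min)
  ch_max <- apply(ws_all$tensor[fit_idx, , , drop = FALSE], 3L, max)
  ws_all$tensor <- scale_tensor(ws_all$tensor, ch_min, ch_max, pp$range)
  # sigmoid-output extractors need [0,1]; clip val/test overshoot from
  # train-only scaling statistics
  ws_all$tensor[] <- pmin(pmax(ws_all$tensor, pp$range[1L]), pp$range[2L])
  ws_train <- subset_windows(ws_all, train_idx)
  ws_val <- subset_windows(ws_all, val_idx)
  ws_test <- subset_windows(ws_all, test_idx)
  if (identical(pp$smote, "train")) {
    ws_train <- smote_upsample(ws_train, pp$smote_k, seed = config$seed + 2L,
                               scope = "train_only")
  } else if (identical(pp$smote, "all")) {
    ws_train <- smote_upsample(ws_train, pp$smote_k, seed = config$seed + 2L,
                               scope = "all")
    ws_all <- smote_upsample(ws_all, pp$smote_k, seed = config$seed + 2L,
                             scope = "all")
  }

  # -- train extractor --------------------------------------------------------
  ex <- config$extractor
  extractor <- stage("train", {
    log_stage("train: %s, %d epochs", ex$family, ex$epochs)
    spec <- build_spec(ex$family, c(pp$window_len, sim$n_channels),
                       n_classes = length(unique(ws_train$window_labels)),
                       latent_dim = ex$latent_dim, overrides = ex$overrides)
    train_supervised(spec, ws_train, ws_val, epochs = ex$epochs,
                     seed = config$seed + 3L)
  })
  ckpt <- file.path(run_dir, "extractor.json")
  save_extractor(extractor, ckpt)
  artifacts <- c(artifacts, ckpt)
  class_acc <- if (dim(ws_test$tensor)[1L] > 0L)
    classify(extractor, ws_test)$accuracy else NA_real_

  # -- extract ----------------------------------------------------------------
  latent <- stage("extract", encode(extractor, ws_all))
  latent_csv <- file.path(run_dir, "latent.csv")
  utils::write.csv(
    data.frame(window_id = seq_len(nrow(latent$matrix)),
               label = latent$source_labels, latent$matrix),
    latent_csv, row.names = FALSE
  )
  artifacts <- c(artifacts, latent_csv)

  # -- cluster ----------------------------------------------------------------
  cl <- config$cluster
  result <- stage("cluster", {
    log_stage("cluster: %s, k = %d", cl$method, cl$k)
    if (identical(cl$method, "dec")) {
      dec_fit(latent, cl$k,
              pretrain_epochs = cl$pretrain_epochs %||% 50L,
              update_interval = cl$update_interval %||% 140L,
              tol = cl$tol %||% 0.001, max_iter = cl$max_iter %||% 20000L,
              seed = config$seed + 4L, alpha = cl$alpha)
    } else {
      kmeans_fit(latent, cl$k, n_init = cl$n_init, seed = config$seed + 4L,
                 alpha = cl$alpha)
    }
  })
  assign_csv <- file.path(run_dir, "assignments.csv")
  Q <- result$Q$Q
  colnames(Q) <- sprintf("q_%d", seq_len(ncol(Q)))
  utils::write.csv(
    data.frame(window_id = seq_len(length(result$hard_labels)),
               hard_label = result$hard_labels, Q),
    assign_csv, row.names = FALSE
  )
  artifacts <- c(artifacts, assign_csv)

  # -- evaluate ---------------------------------------------------------------
  report <- NULL
  if (isTRUE(config$evaluate$enabled)) {
    report <- stage("evaluate",
                    evaluate_clustering(latent$source_labels, result$hard_labels))
    report_json <- file.path(run_dir, "report.json")
    jsonlite::write_json(
      c(unclass(report), list(classification_accuracy = class_acc,
                              schema_version = 1L)),
      report_json, auto_unbox = TRUE, digits = NA
    )
    artifacts <- c(artifacts, report_json)
    log_stage("evaluate: NMI %.3f  ARI %.3f  acc %.3f", report$nmi, report$ari,
              report$accuracy)
  }

  # -- visualize --------------------------------------------------------------
  if (isTRUE(config$viz$enabled)) {
    tree_path <- stage("visualize", {
      g <- knn_graph(latent, min(config$viz$k, nrow(latent$matrix) - 1L))
      tree <- mst(g, node_labels = latent$source_labels)
      out <- file.path(run_dir, "tree.graphml")
      export_graph(tree, latent$source_labels, result$hard_labels, out)
      out
    })
    artifacts <- c(artifacts, tree_path)
  }

  # -- manifest ---------------------------------------------------------------
  manifest <- list(
    package = "harclust",
    version = as.character(utils::packageVersion("harclust")),
    r_version = R.version.string,
    config = config,
    artifacts = as.list(tools::md5sum(artifacts))
  )
  manifest_json <- file.path(run_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_json, auto_unbox = TRUE, digits = NA)

  list(report = report, classification_accuracy = class_acc, result = result,
       run_dir = run_dir, manifest = manifest)
}

#' Reproduce the UCI-HAR experiment (external data required)
#'
#' Convenience wrapper for users who have downloaded the UCI HAR raw-signal
#' dataset: trains the hybrid conv+LSTM extractor on the train split,
#' encodes the test split and clusters with K-Means (k = 6), reporting
#' NMI/ARI for comparison with published results. Not part of the test
#' suite — it needs the external download.
#'
#' @param uci_root Path to the extracted `UCI HAR Dataset` directory.
#' @param epochs,seed Training control.
#' @return An `eval_report` for the test split.
#' @export
reproduce_uci <- function(uci_root, epochs = 30L, seed = 1L) {
  train <- read_uci_har_dir(file.path(uci_root, "train"), "train")
  test <- read_uci_har_dir(file.path(uci_root, "test"), "test")
  ch_min <- apply(train$tensor, 3L, min)
  ch_max <- apply(train$tensor, 3L, max)
  train$tensor <- scale_tensor(train$tensor, ch_min, ch_max)
  test$tensor <- pmin(pmax(scale_tensor(test$tensor, ch_min, ch_max), 0), 1)
  spec <- build_spec("hybrid_conv_lstm", c(128L, 9L), n_classes = 6L,
                     overrides = list(bidirectional = TRUE))
  model <- train_supervised(spec, train, test, epochs = epochs, seed = seed)
  latent <- encode(model, test)
  res <- kmeans_fit(latent, k = 6L, seed = seed)
  evaluate_clustering(latent$source_labels, res$hard_labels)
}
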