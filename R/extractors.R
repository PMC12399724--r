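# Feature-extractor family: spec construction, network assembly, training
# (supervised classification or reconstruction), latent encoding.
#
# Families:
#   cnn2d            two 2-D convolution blocks (conv + max-pool + batchnorm)
#                    on the window reshaped to a [time x 3 x 3] sensor image
#   mlp_ae           fully connected autoencoder, 32-d bottleneck
#   lstm_ae          1-D conv front end, stacked LSTM encoder (128, 64),
#                    mirrored recurrent decoder
#   hybrid_conv_lstm 1-D convolutional encoder feeding an LSTM classifier
#                    with a dense bridge to the latent space
#   timedist_te      time-distributed convolutional slices feeding an LSTM
#   tri_head_te      three conv heads (kernels 5/7/11) at different temporal
#                    granularities, concatenated into two BiLSTM layers

EXTRACTOR_FAMILIES <- c(
  "cnn2d", "mlp_ae", "lstm_ae", "hybrid_conv_lstm", "timedist_te", "tri_head_te"
)

#' Build a fully resolved feature-extractor specification
#'
#' Resolves every layer size for the requested family, applying documented
#' defaults for anything not fixed by the architecture (64/32 convolution
#' filters, dropout 0.3, pool 2 or 4, dense bridge 128, Adam learning rate
#' 1e-3). Validates that the window length is compatible with the family's
#' pooling factor, erroring with a suggested padded length otherwise.
#'
#' @param family One of `"cnn2d"`, `"mlp_ae"`, `"lstm_ae"`,
#'   `"hybrid_conv_lstm"`, `"timedist_te"`, `"tri_head_te"`.
#' @param input_shape Length-2 integer `(window_len, n_channels)`.
#' @param n_classes Number of activity classes for the supervised head.
#' @param latent_dim Latent feature dimension (default 32, the MLP-AE
#'   bottleneck width; all families project to this for a uniform
#'   clustering interface).
#' @param overrides Named list of hyperparameter overrides. Recognised keys
#'   include `conv_filters`, `kernel`, `pool`, `dropout`, `dense_units`,
#'   `lstm_units`, `head_kernels`, `recurrent_dropout`, `bidirectional`,
#'   `hidden`, `lr`, `batch_size`.
#' @return An object of class `extractor_spec` with all sizes concrete.
#' @export
build_spec <- function(family, input_shape, n_classes, latent_dim = 32L,
                       overrides = list()) {
  family <- match.arg(family, EXTRACTOR_FAMILIES)
  stopifnot(length(input_shape) == 2L)
  w <- check_count(input_shape[1L], "window_len")
  nc <- check_count(input_shape[2L], "n_channels")
  n_classes <- check_count(n_classes, "n_classes", lower = 2L)
  latent_dim <- check_count(latent_dim, "latent_dim")

  hp <- switch(family,
    mlp_ae = list(hidden = c(256L, 64L)),
    cnn2d = list(conv_filters = c(32L, 64L), kernel = c(3L, 3L), pool = c(2L, 1L)),
    lstm_ae = list(conv_filters = 32L, kernel = 5L, pool = 4L,
                   lstm_units = c(128L, 64L), bidirectional = FALSE),
    hybrid_conv_lstm = list(conv_filters = c(32L, 64L), kernel = 5L, pool = 2L,
                            lstm_units = 64L, dense_units = 128L,
                            bidirectional = FALSE),
    timedist_te = list(conv_filters = c(64L, 32L), kernel = 5L, pool = 2L,
                       dropout = 0.3, lstm_units = 64L, bidirectional = FALSE),
    tri_head_te = list(head_kernels = c(5L, 7L, 11L), conv_filters = 32L,
                       dropout = 0.3, pool = 4L, lstm_units = c(64L, 32L),
                       dense_units = 64L, recurrent_dropout = 0.2,
                       bidirectional = TRUE)
  )
  hp$lr <- 1e-3
  hp$batch_size <- 64L
  unknown <- setdiff(names(overrides), c(names(hp), "dropout"))
  if (length(unknown) > 0L)
    stop_bad_arg("unknown hyperparameter override(s): %s",
                 paste(unknown, collapse = ", "))
  hp[names(overrides)] <- overrides

  # shape feasibility
  if (family == "cnn2d") {
    if (nc != 9L)
      stop_bad_arg("cnn2d expects 9 channels (3 sensors x 3 axes), got %d", nc)
    div <- prod(rep(hp$pool[1L], 2L))
    if (w %% div != 0L)
      stop_bad_arg("cnn2d needs window_len divisible by %d; pad %d to %d",
                   div, w, ceiling(w / div) * div)
  }
  pool_total <- switch(family,
    lstm_ae = hp$pool,
    hybrid_conv_lstm = hp$pool^2L,
    timedist_te = hp$pool^2L,
    tri_head_te = hp$pool,
    1L
  )
  if (w %% pool_total != 0L)
    stop_bad_arg("%s needs window_len divisible by %d; pad %d to %d",
                 family, pool_total, w, ceiling(w / pool_total) * pool_total)

  structure(
    list(family = family, input_shape = c(w, nc), n_classes = n_classes,
         latent_dim = latent_dim, hyperparams = hp),
    class = "extractor_spec"
  )
}

#' @export
print.extractor_spec <- function(x, ...) {
  cat(sprintf(
    "<extractor_spec> %s: input [%d x %d] -> latent %d, %d classes\n",
    x$family, x$input_shape[1], x$input_shape[2], x$latent_dim, x$n_classes
  ))
  invisible(x)
}

maybe_bilstm <- function(bidirectional, units, return_sequences = FALSE,
                         recurrent_dropout = 0) {
  if (isTRUE(bidirectional)) nn_bilstm(units, return_sequences, recurrent_dropout)
  else nn_lstm(units, return_sequences, recurrent_dropout)
}

# returns list(encoder = list of layers, head = ..., decoder = ... or NULL)
assemble_layers <- function(spec) {
  hp <- spec$hyperparams
  w <- spec$input_shape[1L]; nc <- spec$input_shape[2L]
  ld <- spec$latent_dim
  enc <- dec <- NULL
  switch(spec$family,
    mlp_ae = {
      enc <- c(
        list(nn_flatten()),
        lapply(hp$hidden, function(u) nn_dense(u, "relu")),
        list(nn_dense(ld, "linear"))
      )
      dec <- c(
        lapply(rev(hp$hidden), function(u) nn_dense(u, "relu")),
        list(nn_dense(w * nc, "sigmoid"), nn_reshape(c(w, nc)))
      )
    },
    cnn2d = {
      enc <- list(
        nn_reshape(c(w, 3L, 3L)),
        nn_conv2d(hp$conv_filters[1L], hp$kernel, "relu"),
        nn_maxpool2d(hp$pool),
        nn_batchnorm(),
        nn_conv2d(hp$conv_filters[2L], hp$kernel, "relu"),
        nn_maxpool2d(hp$pool),
        nn_batchnorm(),
        nn_flatten(),
        nn_dense(ld, "relu")
      )
    },
    lstm_ae = {
      tp <- w %/% hp$pool
      enc <- list(
        nn_conv1d(hp$conv_filters, hp$kernel, "relu"),
        nn_maxpool1d(hp$pool),
        maybe_bilstm(hp$bidirectional, hp$lstm_units[1L], return_sequences = TRUE),
        maybe_bilstm(hp$bidirectional, hp$lstm_units[2L]),
        nn_dense(ld, "relu")
      )
      dec <- list(
        nn_dense(hp$lstm_units[2L], "relu"),
        nn_repeat(tp),
        nn_lstm(hp$lstm_units[2L], return_sequences = TRUE),
        nn_lstm(hp$lstm_units[1L], return_sequences = TRUE),
        nn_upsample1d(hp$pool),
        nn_dense(nc, "sigmoid")
      )
    },
    hybrid_conv_lstm = {
      tp <- w %/% hp$pool^2L
      enc <- list(
        nn_conv1d(hp$conv_filters[1L], hp$kernel, "relu"),
        nn_maxpool1d(hp$pool),
        nn_conv1d(hp$conv_filters[2L], hp$kernel, "relu"),
        nn_maxpool1d(hp$pool),
        maybe_bilstm(hp$bidirectional, hp$lstm_units[1L]),
        nn_dense(hp$dense_units, "relu"),
        nn_dense(ld, "linear")
      )
      dec <- list(
        nn_dense(hp$dense_units, "relu"),
        nn_dense(tp * hp$conv_filters[2L], "relu"),
        nn_reshape(c(tp, hp$conv_filters[2L])),
        nn_upsample1d(hp$pool),
        nn_conv1d(hp$conv_filters[1L], hp$kernel, "relu"),
        nn_upsample1d(hp$pool),
        nn_dense(nc, "sigmoid")
      )
    },
    timedist_te = {
      enc <- list(
        nn_conv1d(hp$conv_filters[1L], hp$kernel, "relu"),
        nn_dropout(hp$dropout),
        nn_maxpool1d(hp$pool),
        nn_conv1d(hp$conv_filters[2L], hp$kernel, "relu"),
        nn_dropout(hp$dropout),
        nn_maxpool1d(hp$pool),
        maybe_bilstm(hp$bidirectional, hp$lstm_units[1L]),
        nn_dense(ld, "relu")
      )
    },
    tri_head_te = {
      heads <- lapply(hp$head_kernels, function(kw) {
        list(
          nn_conv1d(hp$conv_filters, kw, "relu"),
          nn_dropout(hp$dropout),
          nn_maxpool1d(hp$pool)
        )
      })
      enc <- list(
        nn_multihead(heads),
        maybe_bilstm(hp$bidirectional, hp$lstm_units[1L], return_sequences = TRUE,
                     recurrent_dropout = hp$recurrent_dropout),
        maybe_bilstm(hp$bidirectional, hp$lstm_units[2L],
                     recurrent_dropout = hp$recurrent_dropout),
        nn_dense(hp$dense_units, "relu"),
        nn_batchnorm(),
        nn_dense(ld, "linear")
      )
    }
  )
  list(
    encoder = enc,
    head = list(nn_dense(spec$n_classes, "linear")),
    decoder = dec
  )
}

new_trained_extractor <- function(spec, model, encoder_len, history, seed, mode) {
  structure(
    list(spec = spec, model = model, encoder_len = encoder_len,
         training_history = history, seed = seed, mode = mode),
    class = "trained_extractor"
  )
}

#' @export
print.trained_extractor <- function(x, ...) {
  h <- x$training_history
  cat(sprintf(
    "<trained_extractor> %s (%s), %d epochs, final loss %.4f%s\n",
    x$spec$family, x$mode, nrow(h), h$loss[nrow(h)],
    if (!is.null(h$val_accuracy) && !anyNA(h$val_accuracy))
      sprintf(", val acc %.3f", h$val_accuracy[nrow(h)]) else ""
  ))
  invisible(x)
}

check_ws_shape <- function(ws, spec) {
  d <- dim(ws$tensor)
  if (d[2L] != spec$input_shape[1L] || d[3L] != spec$input_shape[2L])
    stop_bad_arg("window set shape [%d x %d] does not match spec input [%d x %d]",
                 d[2L], d[3L], spec$input_shape[1L], spec$input_shape[2L])
}

#' Train a feature extractor with supervised classification
#'
#' Minimizes categorical cross-entropy with Adam over mini-batches, the
#' phase-1 training regime: the classification task forces the encoder to
#' organize its latent space by activity, after which the head is discarded
#' and the latent features feed the unsupervised clustering phase.
#'
#' @param spec An [build_spec()] result.
#' @param train,val [window_set]s for training and validation (pass
#'   `val = NULL` to skip validation metrics).
#' @param epochs Number of passes over the training set (`>= 1`).
#' @param seed Integer seed controlling weight initialization, shuffling
#'   and dropout.
#' @param verbose Print per-epoch progress.
#' @return A `trained_extractor` whose `training_history` data frame has one
#'   row per epoch (`loss`, `accuracy`, `val_loss`, `val_accuracy`).
#' @export
train_supervised <- function(spec, train, val = NULL, epochs = 30L, seed = 0L,
                             verbose = FALSE) {
  stopifnot(inherits(spec, "extractor_spec"), inherits(train, "window_set"))
  epochs <- check_count(epochs, "epochs")
  check_ws_shape(train, spec)
  y <- train$window_labels
  if (length(unique(y)) < 2L)
    stop_bad_arg("training set covers a single class; supervised training needs >= 2")
  if (max(y) + 1L > spec$n_classes)
    stop_bad_arg("label %d exceeds n_classes = %d", max(y), spec$n_classes)
  hp <- spec$hyperparams
  with_seed(seed, {
    parts <- assemble_layers(spec)
    layers <- c(parts$encoder, parts$head)
    model <- nn_build(layers, spec$input_shape)
    plist <- collect_param_layers(model$layers)
    opt <- adam_new(lr = hp$lr)
    n <- dim(train$tensor)[1L]
    bs <- min(hp$batch_size, n)
    hist <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, n, bs)) {
        bidx <- ord[start:min(start + bs - 1L, n)]
        xb <- train$tensor[bidx, , , drop = FALSE]
        fw <- nn_forward(model, xb, training = TRUE)
        lg <- ce_loss_grad(fw$out, y[bidx])
        nn_backward(model, fw$caches, lg$grad)
        adam_step(opt, plist)
        ep_loss <- ep_loss + lg$loss * length(bidx)
        ep_correct <- ep_correct + sum(max.col(fw$out, ties.method = "first") == y[bidx] + 1L)
      }
      row <- data.frame(
        epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n,
        val_loss = NA_real_, val_accuracy = NA_real_
      )
      if (!is.null(val)) {
        fv <- nn_forward(model, val$tensor, training = FALSE)
        lv <- ce_loss_grad(fv$out, val$window_labels)
        row$val_loss <- lv$loss
        row$val_accuracy <- mean(
          max.col(fv$out, ties.method = "first") == val$window_labels + 1L
        )
      }
      hist[[ep]] <- row
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f%s", ep, row$loss, row$accuracy,
                        if (!is.na(row$val_accuracy))
                          sprintf("  val_acc %.3f", row$val_accuracy) else ""))
    }
    new_trained_extractor(spec, model, length(parts$encoder),
                          do.call(rbind, hist), seed, "supervised")
  })
}

#' Train an autoencoder feature extractor by reconstruction
#'
#' Minimizes mean squared reconstruction error with Adam. The decoder ends
#' in a sigmoid, so inputs must lie in `[0, 1]` — MinMax-scale the frame
#' first ([fit_scaler()] with `target_range = c(0, 1)`).
#'
#' @param spec A spec whose family has a decoder: `mlp_ae`, `lstm_ae` or
#'   `hybrid_conv_lstm`.
#' @param data Training [window_set] (labels are ignored).
#' @param epochs,seed,verbose As in [train_supervised()].
#' @return A `trained_extractor` with `mode = "autoencoder"`; its history
#'   records the per-epoch reconstruction `loss`.
#' @export
train_autoencoder <- function(spec, data, epochs = 30L, seed = 0L, verbose = FALSE) {
  stopifnot(inherits(spec, "extractor_spec"), inherits(data, "window_set"))
  epochs <- check_count(epochs, "epochs")
  if (!spec$family %in% c("mlp_ae", "lstm_ae", "hybrid_conv_lstm"))
    stop_bad_arg("family '%s' has no reconstruction decoder", spec$family)
  check_ws_shape(data, spec)
  rng <- range(data$tensor)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop_bad_arg(
      "inputs span [%.3f, %.3f] but the sigmoid output expects [0, 1]; rescale with fit_scaler(target_range = c(0, 1))",
      rng[1L], rng[2L]
    )
  hp <- spec$hyperparams
  with_seed(seed, {
    parts <- assemble_layers(spec)
    layers <- c(parts$encoder, parts$decoder)
    model <- nn_build(layers, spec$input_shape)
    plist <- collect_param_layers(model$layers)
    opt <- adam_new(lr = hp$lr)
    n <- dim(data$tensor)[1L]
    bs <- min(hp$batch_size, n)
    hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, bs)) {
        bidx <- ord[start:min(start + bs - 1L, n)]
        xb <- data$tensor[bidx, , , drop = FALSE]
        fw <- nn_forward(model, xb, training = TRUE)
        lg <- mse_loss_grad(fw$out, xb)
        nn_backward(model, fw$caches, lg$grad)
        adam_step(opt, plist)
        ep_loss <- ep_loss + lg$loss * length(bidx)
      }
      hist[ep] <- ep_loss / n
      if (verbose) message(sprintf("epoch %3d  mse %.5f", ep, hist[ep]))
    }
    new_trained_extractor(spec, model, length(parts$encoder),
                          data.frame(epoch = seq_len(epochs), loss = hist),
                          seed, "autoencoder")
  })
}

#' Encode windows into latent features
#'
#' Runs the trained encoder (dropout disabled, batch statistics frozen) on
#' each window independently, producing the `n_windows x latent_dim` matrix
#' that is the interface between feature extraction and clustering.
#'
#' @param model A `trained_extractor`.
#' @param ws A [window_set] matching the spec's input shape.
#' @return An object of class `latent_features`: list with `matrix` and
#'   `source_labels` (carried through for evaluation only).
#' @export
encode <- function(model, ws) {
  stopifnot(inherits(model, "trained_extractor"), inherits(ws, "window_set"))
  check_ws_shape(ws, model$spec)
  fw <- nn_forward(model$model, ws$tensor, training = FALSE,
                   upto = model$encoder_len)
  structure(
    list(matrix = fw$out, source_labels = ws$window_labels,
         label_names = ws$label_names),
    class = "latent_features"
  )
}

#' @export
print.latent_features <- function(x, ...) {
  cat(sprintf("<latent_features> %d windows x %d dims\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Classify windows with a supervised extractor
#'
#' Argmax over the classification head's scores; ties resolve to the lowest
#' class index.
#'
#' @param model A `trained_extractor` trained with [train_supervised()].
#' @param ws A non-empty [window_set].
#' @return List with `labels` (0-based predictions) and `accuracy` against
#'   the window labels.
#' @export
classify <- function(model, ws) {
  stopifnot(inherits(model, "trained_extractor"), inherits(ws, "window_set"))
  if (model$mode != "supervised")
    stop_bad_arg("classify() needs a supervised extractor (got '%s')", model$mode)
  if (dim(ws$tensor)[1L] < 1L) stop_bad_arg("empty window set")
  check_ws_shape(ws, model$spec)
  fw <- nn_forward(model$model, ws$tensor, training = FALSE)
  pred <- max.col(fw$out, ties.method = "first") - 1L
  list(labels = pred, accuracy = mean(pred == ws$window_labels))
}

# checkpointing ---------------------------------------------------------------

#' Save / load a trained extractor as a JSON checkpoint
#'
#' The checkpoint is a portable text container embedding the resolved spec
#' manifest, training metadata and every weight array (with dimensions), so
#' a model can be reloaded without any binary serialization.
#'
#' @param model A `trained_extractor`.
#' @param path Output `.json` path.
#' @return `path` (save) or the restored `trained_extractor` (load).
#' @export
save_extractor <- function(model, path) {
  stopifnot(inherits(model, "trained_extractor"))
  plist <- collect_param_layers(model$model$layers)
  weights <- lapply(plist, function(l) {
    lapply(l$params, function(p) list(dim = dim(p) %||% length(p), data = as.numeric(p)))
  })
  payload <- list(
    format = "harclust-extractor-v1",
    spec = model$spec[c("family", "input_shape", "n_classes", "latent_dim", "hyperparams")],
    mode = model$mode, seed = model$seed, encoder_len = model$encoder_len,
    training_history = model$training_history,
    weights = weights
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_extractor
#' @export
load_extractor <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (!identical(payload$format, "harclust-extractor-v1"))
    stop_bad_arg("'%s' is not a harclust extractor checkpoint", path)
  sp <- payload$spec
  spec <- build_spec(sp$family, sp$input_shape, sp$n_classes, sp$latent_dim,
                     overrides = sp$hyperparams[
                       setdiff(names(sp$hyperparams), c("lr", "batch_size"))
                     ])
  spec$hyperparams$lr <- sp$hyperparams$lr
  spec$hyperparams$batch_size <- sp$hyperparams$batch_size
  parts <- assemble_layers(spec)
  layers <- switch(payload$mode,
    supervised = c(parts$encoder, parts$head),
    autoencoder = c(parts$encoder, parts$decoder)
  )
  model <- nn_build(layers, spec$input_shape, seed = 0L)
  plist <- collect_param_layers(model$layers)
  if (length(plist) != length(payload$weights))
    stop_bad_arg("checkpoint weight count mismatch")
  for (i in seq_along(plist)) {
    for (nm in names(plist[[i]]$params)) {
      w <- payload$weights[[i]][[nm]]
      arr <- array(as.numeric(w$data), unlist(w$dim))
      if (length(unlist(w$dim)) == 1L) arr <- as.numeric(w$data)
      plist[[i]]$params[[nm]] <- arr
    }
  }
  hist <- do.call(rbind, lapply(payload$training_history, function(r) {
    as.data.frame(lapply(r, function(x) if (is.null(x)) NA else x))
  }))
  new_trained_extractor(spec, model, payload$encoder_len, hist,
                        payload$seed, payload$mode)
}
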