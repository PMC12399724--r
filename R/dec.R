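# Deep embedded clustering: stacked autoencoder pretraining, k-means
# centroid initialization, then joint refinement of encoder weights and
# centroids by gradient descent on KL(P || Q).

#' DEC autoencoder architecture
#'
#' The stacked autoencoder used by deep embedded clustering: encoder widths
#' 500, 500, 2000 down to a 10-dimensional bottleneck, decoder mirrored.
#' Hidden layers are ReLU; the bottleneck and reconstruction layers are
#' linear.
#'
#' @param input_dim Input feature dimension.
#' @param latent_dim Bottleneck width (default 10).
#' @param encoder_widths Hidden-layer widths (default `c(500, 500, 2000)`).
#' @return An object of class `dec_spec` with the full `layer_widths`
#'   vector, e.g. `c(180, 500, 500, 2000, 10, 2000, 500, 500, 180)` for
#'   `input_dim = 180`.
#' @export
dec_build_autoencoder <- function(input_dim, latent_dim = 10L,
                                  encoder_widths = c(500L, 500L, 2000L)) {
  input_dim <- check_count(input_dim, "input_dim")
  latent_dim <- check_count(latent_dim, "latent_dim")
  structure(
    list(
      input_dim = input_dim,
      encoder_widths = as.integer(encoder_widths),
      latent_dim = latent_dim,
      layer_widths = c(input_dim, encoder_widths, latent_dim,
                       rev(encoder_widths), input_dim)
    ),
    class = "dec_spec"
  )
}

#' @export
print.dec_spec <- function(x, ...) {
  cat("<dec_spec> layers:", paste(x$layer_widths, collapse = " -> "), "\n")
  invisible(x)
}

dec_assemble <- function(spec) {
  enc <- c(
    lapply(spec$encoder_widths, function(u) nn_dense(u, "relu")),
    list(nn_dense(spec$latent_dim, "linear"))
  )
  dec <- c(
    lapply(rev(spec$encoder_widths), function(u) nn_dense(u, "relu")),
    list(nn_dense(spec$input_dim, "linear"))
  )
  list(encoder = enc, decoder = dec)
}

# Analytic gradients of KL(P || Q) under the Student-t assignment, with
# respect to the embedded points and the centroids.
dec_kl_grads <- function(Z, mu, P, alpha = 1) {
  d2 <- sq_dist(Z, mu)
  S <- (1 + d2 / alpha)^(-(alpha + 1) / 2)
  Q <- S / rowSums(S)
  U <- 1 / (1 + d2 / alpha)
  W <- U * (P - Q)
  coef <- (alpha + 1) / alpha
  dz <- coef * (rowSums(W) * Z - W %*% mu)
  dmu <- -coef * (crossprod(W, Z) - colSums(W) * mu)
  list(dz = dz, dmu = dmu, Q = Q)
}

#' Fit deep embedded clustering
#'
#' Three stages: (1) pretrain the [dec_build_autoencoder()] stacked
#' autoencoder by mean-squared reconstruction error; (2) initialize `k`
#' centroids by K-Means on the embeddings; (3) alternate — compute the
#' Student-t soft assignment `Q`, every `update_interval` mini-batch steps
#' recompute the sharpened target `P` ([target_distribution()]), and take
#' Adam steps on `KL(P || Q)` with respect to both encoder weights and
#' centroids. Refinement stops when the fraction of points whose hard
#' assignment changed between consecutive target updates falls below `tol`,
#' or at `max_iter` mini-batch iterations.
#'
#' @param Z `latent_features`, or a numeric matrix of raw/extracted feature
#'   vectors (one row per window).
#' @param k Number of clusters (`>= 2`).
#' @param pretrain_epochs Autoencoder pretraining epochs (default 300).
#' @param update_interval Mini-batch steps between target-distribution
#'   refreshes (default 140).
#' @param tol Label-change fraction below which refinement stops
#'   (default 0.001, i.e. 0.1%).
#' @param max_iter Refinement iteration cap (default 20000).
#' @param seed Integer seed.
#' @param alpha Student-t degrees of freedom (default 1).
#' @param batch_size Mini-batch size (default 256).
#' @param lr Adam learning rate for autoencoder pretraining (default 1e-3).
#' @param refine_lr Adam learning rate for the KL refinement stage
#'   (default 1e-4). Refinement is deliberately gentle: the self-training
#'   target sharpens after every update, and large steps overshoot it.
#' @return A `cluster_result` with, in addition, `history` (KL and
#'   label-change fraction at each target update), `kl_steps` (per-step
#'   mean KL against the current target), `init_labels` (hard labels at
#'   k-means initialization) and `embedding` (the refined embedding).
#' @export
dec_fit <- function(Z, k, pretrain_epochs = 300L, update_interval = 140L,
                    tol = 0.001, max_iter = 20000L, seed = 0L, alpha = 1,
                    batch_size = 256L, lr = 1e-3, refine_lr = 1e-4) {
  X <- as_feature_matrix(Z)
  k <- check_count(k, "k", lower = 2L)
  pretrain_epochs <- check_count(pretrain_epochs, "pretrain_epochs")
  update_interval <- check_count(update_interval, "update_interval")
  max_iter <- check_count(max_iter, "max_iter")
  check_number(tol, "tol", lower = 0)
  n <- nrow(X)
  if (n < k) stop_bad_arg("need at least k = %d points, got %d", k, n)
  spec <- dec_build_autoencoder(ncol(X))
  with_seed(seed, {
    parts <- dec_assemble(spec)
    ae <- nn_build(c(parts$encoder, parts$decoder), spec$input_dim)
    plist_ae <- collect_param_layers(ae$layers)
    opt <- adam_new(lr = lr)
    bs <- min(batch_size, n)

    # stage 1: reconstruction pretraining
    for (ep in seq_len(pretrain_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, bs)) {
        bidx <- ord[start:min(start + bs - 1L, n)]
        xb <- X[bidx, , drop = FALSE]
        fw <- nn_forward(ae, xb, training = TRUE)
        lg <- mse_loss_grad(fw$out, xb)
        nn_backward(ae, fw$caches, lg$grad)
        adam_step(opt, plist_ae)
      }
    }

    # stage 2: k-means initialization in the embedding
    n_enc <- length(parts$encoder)
    encoder <- structure(list(layers = ae$layers[seq_len(n_enc)],
                              in_shape = spec$input_dim,
                              out_shape = spec$latent_dim),
                         class = "nn_model")
    emb <- nn_forward(encoder, X, training = FALSE)$out
    km <- kmeans_fit(emb, k, n_init = 10L, seed = seed + 1L, alpha = alpha)
    mu_layer <- new_layer("centroids")
    mu_layer$params <- list(mu = km$centroids)
    init_labels <- km$hard_labels
    prev_labels <- init_labels

    # stage 3: KL refinement
    plist_ref <- c(collect_param_layers(encoder$layers), list(mu_layer))
    opt_ref <- adam_new(lr = refine_lr)
    P <- NULL
    history <- list()
    kl_steps <- numeric(0)
    it <- 0L
    n_updates <- 0L
    converged <- FALSE
    ord <- sample.int(n)
    pos <- 1L
    while (it < max_iter) {
      if (it %% update_interval == 0L) {
        n_updates <- n_updates + 1L
        emb <- nn_forward(encoder, X, training = FALSE)$out
        sa <- soft_assign(emb, mu_layer$params$mu, alpha)
        labels <- max.col(sa$Q, ties.method = "first") - 1L
        delta <- mean(labels != prev_labels)
        history[[length(history) + 1L]] <- data.frame(
          iter = it, kl = kl_divergence(target_distribution(sa), sa),
          label_change = delta
        )
        P <- target_distribution(sa)
        prev_labels <- labels
        # the first update seeds P (its labels coincide with the k-means
        # init); the stopping rule is evaluated from the second on
        if (n_updates >= 2L && delta < tol) {
          converged <- TRUE
          break
        }
      }
      if (pos + bs - 1L > n) {
        ord <- sample.int(n)
        pos <- 1L
      }
      bidx <- ord[pos:min(pos + bs - 1L, n)]
      pos <- pos + bs
      fw <- nn_forward(encoder, X[bidx, , drop = FALSE], training = TRUE)
      Pb <- P[bidx, , drop = FALSE]
      g <- dec_kl_grads(fw$out, mu_layer$params$mu, Pb, alpha)
      # normalize by batch size so the step scale matches the mean loss
      nn_backward(encoder, fw$caches, g$dz / length(bidx))
      mu_layer$grads <- list(mu = g$dmu / length(bidx))
      adam_step(opt_ref, plist_ref)
      it <- it + 1L
      kl_steps[it] <- kl_divergence(Pb, g$Q) / length(bidx)
    }

    emb <- nn_forward(encoder, X, training = FALSE)$out
    sa <- soft_assign(emb, mu_layer$params$mu, alpha)
    res <- new_cluster_result(
      hard_labels = max.col(sa$Q, ties.method = "first") - 1L,
      Q = sa, centroids = mu_layer$params$mu,
      n_iter = it, converged = converged, alpha = alpha
    )
    res$history <- do.call(rbind, history)
    res$kl_steps <- kl_steps  # per-step mean KL against the current target
    res$init_labels <- init_labels
    res$embedding <- emb
    res
  })
}
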