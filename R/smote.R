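# SMOTE rebalancing of window sets.

#' SMOTE upsampling of minority activity classes
#'
#' Augments every minority class up to the majority-class window count.
#' Each synthetic window is the classic SMOTE convex combination
#' `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`, where `x` is an existing
#' window of the class and `x_nn` one of its `k_neighbors` nearest
#' same-class neighbours under Euclidean distance on the flattened window.
#' Original windows are never modified; an already balanced set is returned
#' unchanged. Deterministic for a fixed seed.
#'
#' @param ws A [window_set].
#' @param k_neighbors Number of same-class nearest neighbours to draw the
#'   interpolation partner from (default 5, the usual SMOTE setting).
#' @param seed Integer seed.
#' @param scope `"all"` upsamples the whole set (rebalancing the entire
#'   dataset); `"train_only"` is the same operation — the caller applies it
#'   to the training split only and leaves the test distribution untouched.
#'   Recorded in the provenance.
#' @return A [window_set] in which every class has the majority count;
#'   synthetic windows are appended after the originals and flagged in the
#'   `synthetic` attribute (logical vector).
#' @export
smote_upsample <- function(ws, k_neighbors = 5L, seed = 0L,
                           scope = c("all", "train_only")) {
  scope <- match.arg(scope)
  stopifnot(inherits(ws, "window_set"))
  k_neighbors <- check_count(k_neighbors, "k_neighbors")
  labels <- ws$window_labels
  counts <- table(labels)
  if (any(counts < 2L))
    stop_bad_arg(
      "class(es) %s have a single window; SMOTE needs >= 2 per class - merge or exclude them",
      paste(names(counts)[counts < 2L], collapse = ", ")
    )
  target <- max(counts)
  d <- dim(ws$tensor)
  flat <- matrix(ws$tensor, d[1L], d[2L] * d[3L])
  synthetic <- rep(FALSE, d[1L])
  if (all(counts == target)) {
    attr(ws, "synthetic") <- synthetic
    return(ws)
  }
  new_rows <- list()
  new_labels <- integer(0)
  with_seed(seed, {
    for (cls in as.integer(names(counts))) {
      idx <- which(labels == cls)
      need <- target - length(idx)
      if (need == 0L) next
      X <- flat[idx, , drop = FALSE]
      k_use <- min(k_neighbors, length(idx) - 1L)
      D <- as.matrix(stats::dist(X))
      diag(D) <- Inf
      nn <- matrix(
        t(apply(D, 1, function(row) order(row)[seq_len(k_use)])),
        nrow = length(idx), ncol = k_use
      )
      base <- idx[((seq_len(need) - 1L) %% length(idx)) + 1L]
      base_pos <- match(base, idx)
      pick <- nn[cbind(base_pos, sample.int(k_use, need, replace = TRUE))]
      u <- stats::runif(need)
      synth <- X[base_pos, , drop = FALSE] +
        u * (X[pick, , drop = FALSE] - X[base_pos, , drop = FALSE])
      new_rows[[length(new_rows) + 1L]] <- synth
      new_labels <- c(new_labels, rep(cls, need))
    }
  })
  add <- do.call(rbind, new_rows)
  out_flat <- rbind(flat, add)
  out <- array(out_flat, c(nrow(out_flat), d[2L], d[3L]))
  res <- window_set(out, c(labels, new_labels), window_len = ws$window_len,
                    step = ws$step, label_names = ws$label_names,
                    channel_names = ws$channel_names,
                    provenance = c(ws$provenance, paste0("smote:", scope)))
  attr(res, "synthetic") <- c(synthetic, rep(TRUE, nrow(add)))
  res
}
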