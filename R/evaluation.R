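# Clustering evaluation: contingency table, NMI, ARI, optimal-mapping
# cluster accuracy.

#' Contingency table of two labelings
#'
#' @param true_labels,pred_labels Equal-length label vectors (any atomic
#'   type; levels are taken in sorted order of appearance).
#' @return Object of class `contingency_table`: list with an integer
#'   matrix `counts` (rows = true classes, columns = predicted clusters),
#'   `n`, and the row/column level vectors.
#' @export
contingency <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop_bad_arg("label vectors must have equal length")
  n <- length(true_labels)
  if (n < 1L) stop_bad_arg("need at least one point")
  tl <- sort(unique(true_labels))
  pl <- sort(unique(pred_labels))
  counts <- matrix(0L, length(tl), length(pl),
                   dimnames = list(as.character(tl), as.character(pl)))
  tab <- table(factor(true_labels, levels = tl), factor(pred_labels, levels = pl))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, n = n, true_levels = tl, pred_levels = pl),
            class = "contingency_table")
}

entropy_nats <- function(sizes, n) {
  p <- sizes[sizes > 0] / n
  -sum(p * log(p))
}

#' Normalized mutual information between two partitions
#'
#' `I(U;V) / sqrt(H(U) * H(V))` computed from the contingency table with
#' natural logarithms (the normalization is base-invariant). When both
#' partitions are a single identical cluster the score is 1; when exactly
#' one partition has zero entropy (so the partitions differ) it is 0.
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(true_labels, pred_labels) {
  ct <- contingency(true_labels, pred_labels)
  n <- ct$n
  a <- rowSums(ct$counts)
  b <- colSums(ct$counts)
  hu <- entropy_nats(a, n)
  hv <- entropy_nats(b, n)
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  nz <- which(ct$counts > 0, arr.ind = TRUE)
  nij <- ct$counts[nz]
  mi <- sum(nij / n * log(nij * n / (a[nz[, 1L]] * b[nz[, 2L]])))
  max(0, min(1, mi / sqrt(hu * hv)))
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting Rand index corrected for chance:
#' `(Index - Expected) / (Max - Expected)` with all pair counts taken from
#' the contingency table. Invariant to relabeling either partition; 1 for
#' identical partitions, about 0 for independent ones.
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @return ARI in `[-1, 1]`.
#' @export
ari <- function(true_labels, pred_labels) {
  ct <- contingency(true_labels, pred_labels)
  ch2 <- function(x) x * (x - 1) / 2
  idx <- sum(ch2(ct$counts))
  a <- sum(ch2(rowSums(ct$counts)))
  b <- sum(ch2(colSums(ct$counts)))
  total <- ch2(ct$n)
  expected <- a * b / total
  maximum <- (a + b) / 2
  if (abs(maximum - expected) < .Machine$double.eps * 4)
    return(if (abs(idx - maximum) < .Machine$double.eps * 4) 1 else 0)
  (idx - expected) / (maximum - expected)
}

# Hungarian algorithm (potentials / augmenting-path form) for the minimum
# assignment of a rectangular cost matrix with nrow <= ncol. Returns for
# each row its assigned column.
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)   # p[j+1]: row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Cluster accuracy under the optimal cluster-to-class mapping
#'
#' Maximum fraction of correctly classified points over all one-to-one
#' mappings from predicted clusters to true classes, found by
#' maximum-weight bipartite matching (Hungarian algorithm) on the
#' contingency table.
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @return Accuracy in `[0, 1]`.
#' @export
cluster_accuracy <- function(true_labels, pred_labels) {
  ct <- contingency(true_labels, pred_labels)
  C <- ct$counts
  s <- max(dim(C))
  pad <- matrix(0, s, s)
  pad[seq_len(nrow(C)), seq_len(ncol(C))] <- C
  assign <- hungarian(max(pad) - pad)
  matched <- sum(pad[cbind(seq_len(s), assign)])
  matched / ct$n
}

#' Full clustering evaluation report
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @return Object of class `eval_report`: list with `nmi`, `ari`,
#'   `accuracy` (optimal-mapping), `n`, `k_true`, `k_pred`.
#' @export
evaluate_clustering <- function(true_labels, pred_labels) {
  structure(
    list(
      nmi = nmi(true_labels, pred_labels),
      ari = ari(true_labels, pred_labels),
      accuracy = cluster_accuracy(true_labels, pred_labels),
      n = length(true_labels),
      k_true = length(unique(true_labels)),
      k_pred = length(unique(pred_labels))
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d  k_true=%d  k_pred=%d\n  NMI %.4f | ARI %.4f | mapped accuracy %.4f\n",
    x$n, x$k_true, x$k_pred, x$nmi, x$ari, x$accuracy
  ))
  invisible(x)
}
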