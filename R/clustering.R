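# Phase-2 clustering on latent features: K-Means with Student-t soft
# assignment, the sharpened target distribution, and the KL objective.

as_feature_matrix <- function(Z) {
  if (inherits(Z, "latent_features")) Z$matrix else as.matrix(Z)
}

new_cluster_result <- function(hard_labels, Q, centroids, n_iter, converged,
                               alpha, inertia = NA_real_) {
  structure(
    list(hard_labels = as.integer(hard_labels), Q = Q, centroids = centroids,
         n_iter = as.integer(n_iter), converged = converged, alpha = alpha,
         inertia = inertia),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d points in %d clusters (%d iterations, %sconverged)\n",
    length(x$hard_labels), nrow(x$centroids), x$n_iter,
    if (x$converged) "" else "not "
  ))
  invisible(x)
}

#' Student-t soft cluster assignment
#'
#' Similarity of each latent point to each centroid under a Student-t
#' kernel with `alpha` degrees of freedom, normalized over clusters:
#' `q_ij = (1 + ||z_i - mu_j||^2 / alpha)^(-(alpha+1)/2) / sum_j'(...)`.
#' `alpha = 1` (a Cauchy kernel) is the usual choice; as `alpha` grows the
#' kernel approaches a Gaussian.
#'
#' @param Z `latent_features` or numeric matrix `[n x d]`.
#' @param centroids Numeric matrix `[k x d]` of cluster centers.
#' @param alpha Positive degrees of freedom (default 1).
#' @return Object of class `soft_assignment`: list with `Q` (`n x k`, rows
#'   sum to 1) and `alpha`.
#' @export
soft_assign <- function(Z, centroids, alpha = 1) {
  check_number(alpha, "alpha", lower = .Machine$double.eps)
  Z <- as_feature_matrix(Z)
  centroids <- as.matrix(centroids)
  stopifnot(ncol(Z) == ncol(centroids))
  d2 <- sq_dist(Z, centroids)
  S <- (1 + d2 / alpha)^(-(alpha + 1) / 2)
  Q <- S / rowSums(S)
  structure(list(Q = Q, alpha = alpha), class = "soft_assignment")
}

# squared Euclidean distances [n x k]
sq_dist <- function(Z, M) {
  zn <- rowSums(Z^2)
  mn <- rowSums(M^2)
  d2 <- outer(zn, mn, `+`) - 2 * Z %*% t(M)
  pmax(d2, 0)
}

#' Sharpened target distribution for KL refinement
#'
#' Squares the soft assignment and renormalizes by cluster frequency:
#' `p_ij = (q_ij^2 / f_j) / sum_j'(q_ij'^2 / f_j')` with `f_j = sum_i q_ij`.
#' This pushes each point toward its high-confidence cluster while
#' discouraging degenerate large clusters.
#'
#' @param Q A `soft_assignment` or `n x k` matrix with rows summing to 1.
#' @return Matrix `P` of the same shape, rows summing to 1.
#' @export
target_distribution <- function(Q) {
  if (inherits(Q, "soft_assignment")) Q <- Q$Q
  f <- colSums(Q)
  W <- sweep(Q^2, 2L, f, `/`)
  W / rowSums(W)
}

#' Kullback-Leibler divergence between assignment distributions
#'
#' `KL(P || Q) = sum_x P(x) * log(P(x) / Q(x))` with natural logs, summed
#' over every entry; `0 * log(0/q)` is taken as 0. Where `P > 0` but
#' `Q == 0` the divergence is infinite (returned with a warning).
#'
#' @param P,Q Numeric matrices (or vectors) of matching shape.
#' @return Non-negative scalar (zero iff `P == Q` row-wise).
#' @export
kl_divergence <- function(P, Q) {
  if (inherits(Q, "soft_assignment")) Q <- Q$Q
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop_bad_arg("P and Q must have matching shapes")
  pos <- P > 0
  if (any(Q[pos] == 0)) {
    warning("P > 0 where Q == 0: KL divergence is infinite", call. = FALSE)
    return(Inf)
  }
  sum(P[pos] * log(P[pos] / Q[pos]))
}

#' K-Means on latent features with Student-t soft assignment
#'
#' Lloyd iterations from k-means++ seeding, best of `n_init` restarts by
#' within-cluster sum of squares. The converged centroids are then scored
#' with the Student-t soft assignment ([soft_assign()]), giving per-point
#' responsibilities alongside the hard labels.
#'
#' @param Z `latent_features` or numeric matrix `[n x d]`, `n >= k`.
#' @param k Number of clusters (`>= 2`).
#' @param n_init Number of restarts (default 10).
#' @param seed Integer seed.
#' @param alpha Student-t degrees of freedom for the soft assignment.
#' @param iter_max Lloyd iteration cap per restart.
#' @return A `cluster_result`: hard labels (0-based), soft assignment `Q`,
#'   centroids, iteration count, convergence flag and total inertia.
#' @export
kmeans_fit <- function(Z, k, n_init = 10L, seed = 0L, alpha = 1, iter_max = 100L) {
  Z <- as_feature_matrix(Z)
  k <- check_count(k, "k", lower = 2L)
  n_init <- check_count(n_init, "n_init")
  n <- nrow(Z)
  if (n < k) stop_bad_arg("need at least k = %d points, got %d", k, n)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      centers <- kmeanspp_init(Z, k)
      km <- tryCatch(
        suppressWarnings(
          stats::kmeans(Z, centers = centers, iter.max = iter_max,
                        algorithm = "Lloyd")
        ),
        error = function(e) NULL  # empty cluster / duplicate centers: retry
      )
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop_bad_arg("all %d k-means restarts failed", n_init)
    sa <- soft_assign(Z, best$centers, alpha)
    new_cluster_result(
      hard_labels = best$cluster - 1L,
      Q = sa, centroids = unname(best$centers),
      n_iter = best$iter, converged = best$iter < iter_max,
      alpha = alpha, inertia = best$tot.withinss
    )
  })
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers by
# sampling points with probability proportional to squared distance from
# the nearest center chosen so far.
kmeanspp_init <- function(Z, k) {
  n <- nrow(Z)
  centers <- matrix(0, k, ncol(Z))
  centers[1L, ] <- Z[sample.int(n, 1L), ]
  d2 <- sq_dist(Z, centers[1L, , drop = FALSE])[, 1L]
  for (j in 2L:k) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- Z[pick, ]
    d2 <- pmin(d2, sq_dist(Z, centers[j, , drop = FALSE])[, 1L])
  }
  centers
}
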