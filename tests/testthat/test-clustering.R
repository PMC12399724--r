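# K-Means with Student-t soft assignment, target distribution, KL.

test_that("soft assignment peaks, normalizes and respects symmetry", {
  mu <- matrix(c(0, 0, 40, 40, -40, 25), 3, 2, byrow = TRUE)
  z <- matrix(c(0, 0), 1, 2)
  q <- soft_assign(z, mu)$Q
  expect_gt(q[1, 1], 0.99)
  expect_equal(rowSums(q), 1)

  # equidistant point: exactly 0.5 / 0.5
  q2 <- soft_assign(matrix(0, 1, 1), matrix(c(-1, 1), 2, 1), alpha = 1)$Q
  expect_equal(as.numeric(q2), c(0.5, 0.5))
  q3 <- soft_assign(matrix(0.5, 1, 1), matrix(c(0, 1), 2, 1), alpha = 1)$Q
  expect_equal(as.numeric(q3), c(0.5, 0.5))

  # rows always normalize
  set.seed(1)
  Z <- matrix(stats::rnorm(40), 20, 2)
  Q <- soft_assign(Z, matrix(stats::rnorm(8), 4, 2), alpha = 2)$Q
  expect_equal(rowSums(Q), rep(1, 20))
  expect_true(all(Q > 0 & Q < 1))
})

test_that("soft assignment limits: Gaussian kernel and degenerate centroids", {
  set.seed(2)
  Z <- matrix(stats::rnorm(20), 10, 2)
  mu <- matrix(stats::rnorm(6), 3, 2)
  big <- soft_assign(Z, mu, alpha = 1e6)$Q
  G <- exp(-harclust:::sq_dist(Z, mu) / 2)
  G <- G / rowSums(G)
  expect_equal(big, G, tolerance = 1e-4)
  same <- soft_assign(Z, mu[c(1, 1, 1), ], alpha = 1)$Q
  expect_equal(same, matrix(1 / 3, 10, 3))
})

test_that("target distribution sharpens and fixes its fixed points", {
  k <- 4
  Qu <- matrix(1 / k, 7, k)
  expect_equal(target_distribution(Qu), Qu)
  Qh <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(target_distribution(Qh), Qh)
  Qb <- rbind(c(0.8, 0.2), c(0.2, 0.8))  # balanced cluster frequencies
  P <- target_distribution(Qb)
  expect_gt(P[1, 1], 0.8)
  expect_equal(rowSums(P), c(1, 1))
  # direct evaluation of the formula
  f <- colSums(Qb)
  w <- Qb^2 / matrix(f, 2, 2, byrow = TRUE)
  expect_equal(P, w / rowSums(w))
})

test_that("KL divergence matches closed forms and Gibbs' inequality", {
  P <- matrix(c(0.3, 0.7, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_equal(kl_divergence(P, P), 0)
  expect_equal(kl_divergence(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)), log(2))
  expect_warning(
    v <- kl_divergence(matrix(c(1, 0), 1), matrix(c(0, 1), 1)), "infinite")
  expect_identical(v, Inf)

  set.seed(3)
  for (rep in 1:20) {
    P <- matrix(stats::runif(12), 3, 4)
    P <- P / rowSums(P)
    Q <- matrix(stats::runif(12), 3, 4)
    Q <- Q / rowSums(Q)
    # brute-force elementwise summation oracle
    brute <- 0
    for (i in 1:3) for (j in 1:4) brute <- brute + P[i, j] * log(P[i, j] / Q[i, j])
    expect_equal(kl_divergence(P, Q), brute)
    expect_gte(kl_divergence(P, Q), 0)
  }
  expect_equal(kl_divergence(P, P), 0)
})

test_that("k-means recovers separated blobs and degenerate geometries", {
  b <- make_blobs(n_per = 100, d = 3, sd = 0.05, seed = 10)
  res <- kmeans_fit(b$X, 3, seed = 0)
  expect_equal(ari(b$y, res$hard_labels), 1.0)
  expect_equal(rowSums(res$Q$Q), rep(1, 300))
  expect_equal(res$hard_labels, max.col(res$Q$Q, ties.method = "first") - 1L)

  # k = n: every point its own cluster, zero inertia
  set.seed(4)
  Z <- matrix(stats::rnorm(10), 5, 2)
  res2 <- kmeans_fit(Z, 5, n_init = 3, seed = 1)
  expect_equal(res2$inertia, 0)
  expect_equal(sort(unique(res2$hard_labels)), 0:4)
  expect_error(kmeans_fit(Z, 6, seed = 1), "at least")

  # duplicating every point leaves the centroids unchanged
  b2 <- make_blobs(n_per = 30, d = 2, sd = 0.1, seed = 11)
  r1 <- kmeans_fit(b2$X, 3, seed = 5)
  r2 <- kmeans_fit(rbind(b2$X, b2$X), 3, seed = 5)
  ord1 <- order(r1$centroids[, 1])
  ord2 <- order(r2$centroids[, 1])
  expect_equal(r1$centroids[ord1, ], r2$centroids[ord2, ], tolerance = 1e-8)
})

test_that("the DEC autoencoder widths follow the stacked design", {
  spec <- dec_build_autoencoder(180)
  expect_equal(spec$layer_widths, c(180, 500, 500, 2000, 10, 2000, 500, 500, 180))
  expect_equal(spec$latent_dim, 10L)
  expect_equal(dec_build_autoencoder(64, latent_dim = 5)$latent_dim, 5L)
})

test_that("analytic KL gradients match finite differences (5 points, k = 2)", {
  set.seed(6)
  Z <- matrix(stats::rnorm(10), 5, 2)
  mu <- matrix(stats::rnorm(4), 2, 2)
  P <- target_distribution(soft_assign(Z, mu, 1))
  g <- harclust:::dec_kl_grads(Z, mu, P, 1)
  kl_of <- function(Zx, mux) kl_divergence(P, soft_assign(Zx, mux, 1)$Q)
  gz <- num_grad(function(zz) kl_of(matrix(zz, 5, 2), mu), Z, eps = 1e-6)
  gm <- num_grad(function(mm) kl_of(Z, matrix(mm, 2, 2)), mu, eps = 1e-6)
  expect_lt(max(abs(g$dz - gz)), 1e-7)
  expect_lt(max(abs(g$dmu - gm)), 1e-7)
})

test_that("DEC stopping contract and row-normalization invariants hold", {
  b <- make_blobs(n_per = 40, d = 4, sd = 0.4, seed = 12)
  expect_error(dec_fit(b$X, 3, max_iter = 0), "max_iter")
  res <- dec_fit(b$X, 3, pretrain_epochs = 5, update_interval = 10,
                 tol = 1, max_iter = 500, seed = 2)
  # tol = 1: stops at the first evaluated target update
  expect_equal(res$n_iter, 10L)
  expect_true(res$converged)
  expect_equal(rowSums(res$Q$Q), rep(1, 120))
  for (r in seq_len(nrow(res$history))) {
    expect_gte(res$history$kl[r], 0)
  }
  expect_true(all(res$kl_steps >= 0))
})
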