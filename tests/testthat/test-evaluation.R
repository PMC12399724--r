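# NMI, ARI, mapped cluster accuracy.

test_that("contingency tables count pairings", {
  ct <- contingency(c(0, 0, 1), c(1, 1, 0))
  expect_equal(unname(ct$counts), matrix(c(0L, 1L, 2L, 0L), 2, 2))
  expect_equal(ct$n, 3)
  ct1 <- contingency(5, 9)
  expect_equal(unname(ct1$counts), matrix(1L, 1, 1))
  set.seed(1)
  a <- sample(0:3, 40, TRUE); b <- sample(0:2, 40, TRUE)
  ct2 <- contingency(a, b)
  expect_equal(unname(rowSums(ct2$counts)), as.integer(table(a)))
  expect_equal(unname(colSums(ct2$counts)), as.integer(table(b)))
  expect_error(contingency(1:3, 1:4), "equal length")
})

test_that("NMI matches a direct entropy computation and its edge cases", {
  expect_equal(nmi(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(nmi(c(0, 0, 1, 1), c(7, 7, 7, 7)), 0.0)
  expect_equal(nmi(c(2, 2, 2), c(2, 2, 2)), 1.0)

  set.seed(2)
  for (rep in 1:10) {
    a <- sample(0:4, 50, TRUE)
    b <- sample(0:3, 50, TRUE)
    # brute-force oracle: direct summation over the joint distribution
    n <- 50
    mi <- 0
    for (u in unique(a)) for (v in unique(b)) {
      nij <- sum(a == u & b == v)
      if (nij > 0)
        mi <- mi + nij / n * log(nij * n / (sum(a == u) * sum(b == v)))
    }
    hu <- -sum(table(a) / n * log(table(a) / n))
    hv <- -sum(table(b) / n * log(table(b) / n))
    expect_equal(nmi(a, b), max(0, min(1, mi / sqrt(hu * hv))), tolerance = 1e-12)
    expect_equal(nmi(a, b), nmi(b, a))  # symmetry
  }
})

test_that("ARI matches brute-force pair counting and label renaming", {
  expect_equal(ari(c(0, 0, 1, 1), c(5, 5, 2, 2)), 1.0)
  # brute-force oracle over all point pairs
  pair_ari <- function(a, b) {
    n <- length(a)
    s11 <- s00 <- s10 <- s01 <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      else if (!same_a && !same_b) s00 <- s00 + 1
      else if (same_a) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
    tot <- s11 + s00 + s10 + s01
    exp_idx <- (s11 + s10) * (s11 + s01) / tot
    max_idx <- ((s11 + s10) + (s11 + s01)) / 2
    (s11 - exp_idx) / (max_idx - exp_idx)
  }
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_equal(pair_ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  set.seed(3)
  for (rep in 1:5) {
    a <- sample(0:2, 12, TRUE)
    b <- sample(0:2, 12, TRUE)
    expect_equal(ari(a, b), pair_ari(a, b), tolerance = 1e-12)
  }
  # invariance to renaming the prediction
  a <- sample(0:3, 30, TRUE); b <- sample(0:3, 30, TRUE)
  expect_equal(ari(a, b), ari(a, 3 - b))
})

test_that("ARI agrees with an independent implementation and chance level", {
  skip_if_not_installed("mclust")
  set.seed(4)
  for (rep in 1:5) {
    a <- sample(0:4, 60, TRUE); b <- sample(0:3, 60, TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  aris <- vapply(1:10, function(r) {
    set.seed(100 + r)
    ari(sample(0:3, 200, TRUE), sample(0:3, 200, TRUE))
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("cluster accuracy equals the exhaustive mapping maximum", {
  expect_equal(cluster_accuracy(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  expect_equal(cluster_accuracy(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1.0)
  # exhaustive k!-mapping oracle for k <= 5: try every one-to-one
  # assignment of predicted clusters to true classes
  perm_acc <- function(a, b) {
    la <- sort(unique(a)); lb <- sort(unique(b))
    s <- max(length(la), length(lb))
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
      }
      out
    }
    ai <- match(a, la)       # true class index per point
    bi <- match(b, lb)       # predicted cluster index per point
    best <- 0
    for (p in perms(seq_len(s))) {
      best <- max(best, mean(ai == p[bi]))
    }
    best
  }
  set.seed(5)
  for (rep in 1:8) {
    k <- sample(2:5, 1)
    a <- sample(seq_len(k) - 1L, 25, TRUE)
    b <- sample(seq_len(k) - 1L, 25, TRUE)
    expect_equal(cluster_accuracy(a, b), perm_acc(a, b))
  }
})

test_that("evaluate_clustering assembles a consistent report", {
  set.seed(6)
  a <- sample(0:2, 40, TRUE); b <- sample(0:2, 40, TRUE)
  rep_ <- evaluate_clustering(a, b)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$n, 40)
  expect_true(rep_$nmi >= 0 && rep_$nmi <= 1)
  expect_true(rep_$ari >= -1 && rep_$ari <= 1)
  expect_true(rep_$accuracy >= 0 && rep_$accuracy <= 1)
})
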