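# Shared fixtures, all generated in code.

# Small window set with well-separated per-class sinusoid signatures.
make_separable_windows <- function(n_per = 30L, k = 2L, w = 32L, nc = 9L,
                                   noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  n <- n_per * k
  tensor <- array(0, c(n, w, nc))
  y <- integer(n)
  t <- (0:(w - 1L)) / 50
  for (i in seq_len(n)) {
    cls <- (i - 1L) %% k
    for (c in seq_len(nc)) {
      f <- 1 + 2 * cls
      tensor[i, , c] <- 0.5 + 0.3 * sin(2 * pi * f * t + c) +
        stats::rnorm(w, 0, noise_sd)
    }
    y[i] <- cls
  }
  tensor <- pmin(pmax(tensor, 0), 1)
  window_set(tensor, y, window_len = w, step = w)
}

# Isotropic Gaussian blobs in d dimensions.
make_blobs <- function(n_per = 100L, d = 10L, k = 3L, sd = 0.6, seed = 3L) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * d), k, d)
  X <- do.call(rbind, lapply(seq_len(k), function(j) {
    sweep(matrix(stats::rnorm(n_per * d, 0, sd), n_per, d), 2, centers[j, ], `+`)
  }))
  list(X = X, y = rep(seq_len(k) - 1L, each = n_per))
}

# Simulated stream segmented into scaled windows (the synthetic study
# conditions: 6 activities, 200 Hz, 120 s, brief cross-fades, small noise).
make_study_windows <- function(stream_seed = 1L, k = 6L, rate_hz = 200,
                               total_s = 120, transition_len_s = 0.25,
                               noise_sd = 0.1, transition_label = "incoming",
                               window_len = 200L, overlap = 0.5) {
  profiles <- make_default_profiles(k, 9L, seed = 7L)
  spec <- stream_spec(
    profiles, rate_hz = rate_hz, transition_len_s = transition_len_s,
    noise_sd = noise_sd, total_duration_s = total_s,
    transition_label = transition_label, seed = stream_seed
  )
  stream <- simulate_stream(spec)
  ws <- segment_windows(stream, window_len, overlap)
  ch_min <- apply(ws$tensor, 3, min)
  ch_max <- apply(ws$tensor, 3, max)
  for (c in seq_len(dim(ws$tensor)[3])) {
    rng <- ch_max[c] - ch_min[c]
    ws$tensor[, , c] <- if (rng > 0) (ws$tensor[, , c] - ch_min[c]) / rng else 0
  }
  list(stream = stream, ws = ws)
}

# central finite-difference gradient of a scalar function of an array
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
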