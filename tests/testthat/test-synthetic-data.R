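# Labeled-stream simulator.

test_that("make_default_profiles gives distinct, deterministic profiles", {
  p2 <- make_default_profiles(2, 9, seed = 0)
  expect_length(p2, 2)
  expect_false(
    isTRUE(all.equal(p2[[1]]$amplitude, p2[[2]]$amplitude)) &&
      isTRUE(all.equal(p2[[1]]$frequency, p2[[2]]$frequency))
  )
  a <- make_default_profiles(6, 9, seed = 1)
  b <- make_default_profiles(6, 9, seed = 1)
  expect_identical(a, b)
  # any pair differs in amplitude or frequency
  for (i in 1:5) for (j in (i + 1):6) {
    expect_false(
      isTRUE(all.equal(a[[i]]$amplitude, a[[j]]$amplitude)) &&
        isTRUE(all.equal(a[[i]]$frequency, a[[j]]$frequency))
    )
  }
  expect_error(make_default_profiles(1, 9, seed = 0), "k")
})

test_that("degenerate single-profile stream is constant at baseline", {
  p <- activity_profile("STD", amplitude = rep(1, 3), frequency = rep(0, 3),
                        phase = rep(0, 3), baseline = c(1, 2, 3),
                        duration_mean = 2, duration_sd = 0.1)
  spec <- stream_spec(list(p), rate_hz = 50, transition_len_s = 0,
                      noise_sd = 0, total_duration_s = 2, seed = 1)
  st <- simulate_stream(spec)
  expect_equal(nrow(st$values), 100)
  for (c in 1:3) expect_true(all(st$values[, c] == c))
  expect_true(all(st$labels == 0))
})

test_that("without cross-fade, label run lengths equal drawn bout lengths", {
  profiles <- make_default_profiles(3, 4, seed = 2)
  spec <- stream_spec(profiles, rate_hz = 50, transition_len_s = 0,
                      noise_sd = 0.1, total_duration_s = 30, seed = 5)
  st <- simulate_stream(spec)
  r <- rle(st$labels)
  bouts <- st$bouts
  # consecutive bouts can repeat an activity only via the chain; with zero
  # diagonal they never do, so runs and bouts correspond 1:1
  expect_equal(length(r$lengths), nrow(bouts))
  expect_equal(r$lengths, as.integer(bouts$end - bouts$start + 1L))
  expect_equal(r$values, bouts$activity)
})

test_that("label proportions match the chain's stationary distribution", {
  # equal expected bout durations, so time shares follow the embedded chain
  P <- matrix(c(0, 0.7, 0.3,
                0.2, 0, 0.8,
                0.5, 0.5, 0), 3, 3, byrow = TRUE)
  profiles <- lapply(1:3, function(i) {
    activity_profile(sprintf("A%d", i), amplitude = rep(0.5, 2),
                     frequency = rep(i - 1, 2), phase = rep(0, 2),
                     baseline = rep(i, 2), duration_mean = 2,
                     duration_sd = 0.2)
  })
  spec <- stream_spec(profiles, transition_matrix = P, rate_hz = 50,
                      transition_len_s = 0, noise_sd = 0,
                      total_duration_s = 60, seed = 42)
  st <- simulate_stream(spec)
  # oracle: leading left eigenvector of the transition matrix
  ev <- eigen(t(P))
  i1 <- which.min(abs(ev$values - 1))
  stat <- Re(ev$vectors[, i1])
  stat <- stat / sum(stat)
  emp <- tabulate(st$labels + 1L, 3) / length(st$labels)
  expect_true(all(abs(emp - stat) <= 0.10))
})

test_that("simulation is deterministic for an identical spec", {
  profiles <- make_default_profiles(4, 9, seed = 3)
  spec <- stream_spec(profiles, rate_hz = 100, transition_len_s = 0.2,
                      noise_sd = 0.2, total_duration_s = 20, seed = 9)
  s1 <- simulate_stream(spec)
  s2 <- simulate_stream(spec)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$values, s2$values)
})

test_that("transition labeling modes behave as configured", {
  profiles <- make_default_profiles(3, 4, seed = 1)
  base <- function(mode) {
    stream_spec(profiles, rate_hz = 50, transition_len_s = 0.5,
                noise_sd = 0, total_duration_s = 30,
                transition_label = mode, seed = 2)
  }
  st_inc <- simulate_stream(base("incoming"))
  expect_true(all(st_inc$labels %in% 0:2))
  st_res <- simulate_stream(base("reserved"))
  expect_true(3 %in% st_res$labels)
  expect_equal(st_res$label_names[4], "TRANS")
  expect_true(nrow(st_res$transitions) >= 1)
  expect_true(all(st_res$transitions$from %in% 0:2))
  # property: several seeds, incoming labels always stay in 0..k-1
  for (s in 1:5) {
    sp <- stream_spec(profiles, rate_hz = 50, transition_len_s = 0.3,
                      noise_sd = 0.1, total_duration_s = 10, seed = s)
    expect_true(all(simulate_stream(sp)$labels %in% 0:2))
  }
})

test_that("per-class window centroids separate when noise vanishes", {
  fx <- make_study_windows(stream_seed = 4, k = 3, rate_hz = 50, total_s = 60,
                           transition_len_s = 0, noise_sd = 0,
                           window_len = 50L, overlap = 0)
  ws <- fx$ws
  flat <- matrix(ws$tensor, dim(ws$tensor)[1], 50 * 9)
  cents <- t(sapply(0:2, function(cl)
    colMeans(flat[ws$window_labels == cl, , drop = FALSE])))
  d <- as.matrix(dist(cents))
  expect_true(all(d[upper.tri(d)] > 0.1))
})

test_that("stream CSV round-trips through the MobiAct reader", {
  fx <- make_study_windows(stream_seed = 2, k = 2, rate_hz = 50, total_s = 1,
                           transition_len_s = 0, noise_sd = 0.05,
                           window_len = 10L, overlap = 0)
  stream <- fx$stream
  stream$values <- stream$values[1:10, , drop = FALSE]
  stream$labels <- stream$labels[1:10]
  path <- tempfile(fileext = ".csv")
  write_stream_csv(stream, path)
  lines <- readLines(path)
  expect_length(lines, 11)  # header + 10 rows
  frame <- read_mobiact_csv(path)
  expect_equal(nrow(frame$values), 10)
  expect_equal(ncol(frame$values), 9)
  expect_lt(max(abs(frame$values - stream$values)), 1e-6)
  # labels survive as the same partition
  expect_equal(frame$label_names[frame$labels + 1L],
               stream$label_names[stream$labels + 1L])
})

test_that("an empty stream writes a header-only CSV", {
  empty <- structure(
    list(values = matrix(numeric(0), 0, 9), labels = integer(0),
         label_names = "STD",
         channel_names = c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y",
                           "gyro_z", "azimuth", "pitch", "roll"),
         rate_hz = 50),
    class = "labeled_stream"
  )
  path <- tempfile(fileext = ".csv")
  write_stream_csv(empty, path)
  expect_length(readLines(path), 1)
})
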