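# Labeled wearable-sensor stream simulator.
#
# Activities are modeled as quasi-periodic multichannel signatures
# (per-channel sinusoid + DC offset + Gaussian noise); a semi-Markov chain
# draws activity bouts (truncated-normal durations, Markov transitions) and
# consecutive bouts are blended by a linear cross-fade so that activities
# flow into each other the way real wearable recordings do.

#' Construct an activity signature profile
#'
#' An `activity_profile` describes one activity class as a per-channel
#' sinusoidal signature: `baseline + amplitude * sin(2*pi*frequency*t + phase)`.
#' Static postures use `frequency = 0` so the signature is a plain offset.
#'
#' @param name Short label, e.g. `"WAL"`, `"STD"`, `"FALL"`.
#' @param amplitude,frequency,phase,baseline Numeric vectors, one entry per
#'   channel. `frequency` is in Hz and must be non-negative.
#' @param duration_mean,duration_sd Mean and standard deviation (seconds) of
#'   the truncated-normal bout duration for this activity.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(name, amplitude, frequency, phase, baseline,
                             duration_mean, duration_sd) {
  n <- length(amplitude)
  if (n < 1L) stop_bad_arg("profile needs at least one channel")
  for (v in list(frequency, phase, baseline)) {
    if (length(v) != n) stop_bad_arg("all channel vectors must share length %d", n)
  }
  if (any(frequency < 0)) stop_bad_arg("`frequency` must be >= 0 elementwise")
  check_number(duration_mean, "duration_mean", lower = .Machine$double.eps)
  check_number(duration_sd, "duration_sd", lower = 0)
  structure(
    list(
      name = as.character(name), amplitude = as.numeric(amplitude),
      frequency = as.numeric(frequency), phase = as.numeric(phase),
      baseline = as.numeric(baseline),
      duration_mean = duration_mean, duration_sd = duration_sd
    ),
    class = "activity_profile"
  )
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf(
    "<activity_profile> %s: %d channels, bout %.1f +/- %.1f s\n",
    x$name, length(x$amplitude), x$duration_mean, x$duration_sd
  ))
  invisible(x)
}

#' Generate a set of distinct default activity profiles
#'
#' Draws `k` activity signatures with pairwise-distinct amplitude/frequency
#' patterns: even-indexed activities are dynamic (walking-like periodic
#' signals at distinct fundamental frequencies), odd-indexed ones are static
#' postures (zero frequency, distinct offsets). Deterministic for a fixed
#' seed.
#'
#' @param k Number of activities, `>= 2`.
#' @param n_channels Number of sensor channels (default 9:
#'   accelerometer xyz, gyroscope xyz, azimuth/pitch/roll).
#' @param seed Integer seed.
#' @return List of `k` [activity_profile] objects.
#' @export
make_default_profiles <- function(k, n_channels = 9L, seed = 0L) {
  k <- check_count(k, "k", lower = 2L)
  n_channels <- check_count(n_channels, "n_channels", lower = 1L)
  with_seed(seed, {
    lapply(seq_len(k), function(i) {
      dynamic <- (i %% 2L) == 1L
      freq_base <- if (dynamic) 0.8 + 0.45 * i else 0
      activity_profile(
        name = sprintf("ACT%02d", i - 1L),
        amplitude = if (dynamic) stats::runif(n_channels, 0.5, 1.5)
                    else stats::runif(n_channels, 0.02, 0.08),
        frequency = rep(freq_base, n_channels) *
          (if (dynamic) stats::runif(n_channels, 0.9, 1.1) else 1),
        phase = stats::runif(n_channels, 0, 2 * pi),
        baseline = stats::rnorm(n_channels, mean = 0.6 * i, sd = 0.15),
        duration_mean = stats::runif(1, 5, 8),
        duration_sd = 1.0
      )
    })
  })
}

#' Specify a simulated labeled sensor stream
#'
#' @param profiles List of [activity_profile] objects (all with the same
#'   channel count), one per activity class.
#' @param transition_matrix Row-stochastic `k x k` matrix of bout-to-bout
#'   transition probabilities. Default: uniform over the other activities.
#' @param class_prior Initial-state probability vector (default uniform).
#' @param rate_hz Sampling rate in Hz (default 200, smartphone-grade IMU).
#' @param transition_len_s Cross-fade duration in seconds between
#'   consecutive bouts (`0` disables blending).
#' @param noise_sd Additive Gaussian noise standard deviation (sensor units).
#' @param total_duration_s Total stream duration in seconds.
#' @param transition_label Either `"incoming"` (cross-fade samples take the
#'   upcoming activity's label; the default, since real HAR datasets rarely
#'   label transitions) or `"reserved"` (cross-fade samples get a dedicated
#'   transition class with index `k`).
#' @param seed Integer seed.
#' @return An object of class `stream_spec`.
#' @export
stream_spec <- function(profiles,
                        transition_matrix = NULL,
                        class_prior = NULL,
                        rate_hz = 200,
                        transition_len_s = 0,
                        noise_sd = 0.05,
                        total_duration_s = 60,
                        transition_label = c("incoming", "reserved"),
                        seed = 0L) {
  if (!is.list(profiles) || length(profiles) < 1L)
    stop_bad_arg("`profiles` must be a non-empty list of activity_profile")
  k <- length(profiles)
  nc <- length(profiles[[1L]]$amplitude)
  for (p in profiles) {
    if (!inherits(p, "activity_profile"))
      stop_bad_arg("`profiles` must contain activity_profile objects")
    if (length(p$amplitude) != nc)
      stop_bad_arg("all profiles must share the channel count %d", nc)
  }
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / max(k - 1L, 1L), k, k)
    diag(transition_matrix) <- 0
    if (k == 1L) transition_matrix <- matrix(1, 1, 1)
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(k, k)))
    stop_bad_arg("`transition_matrix` must be %d x %d", k, k)
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-9))
    stop_bad_arg("each `transition_matrix` row must sum to 1")
  if (any(transition_matrix < 0)) stop_bad_arg("`transition_matrix` must be non-negative")
  class_prior <- class_prior %||% rep(1 / k, k)
  if (length(class_prior) != k || abs(sum(class_prior) - 1) > 1e-9 || any(class_prior < 0))
    stop_bad_arg("`class_prior` must be a length-%d probability vector", k)
  check_number(rate_hz, "rate_hz", lower = .Machine$double.eps)
  check_number(transition_len_s, "transition_len_s", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(total_duration_s, "total_duration_s", lower = .Machine$double.eps)
  structure(
    list(
      profiles = profiles, transition_matrix = transition_matrix,
      class_prior = as.numeric(class_prior), rate_hz = rate_hz,
      transition_len_s = transition_len_s, noise_sd = noise_sd,
      total_duration_s = total_duration_s,
      transition_label = match.arg(transition_label),
      seed = as.integer(seed), n_channels = nc, k = k
    ),
    class = "stream_spec"
  )
}

signature_block <- function(profile, t_sec) {
  # [length(t_sec) x n_channels] noiseless signature values
  nc <- length(profile$amplitude)
  out <- matrix(0, length(t_sec), nc)
  for (c in seq_len(nc)) {
    out[, c] <- profile$baseline[c] +
      profile$amplitude[c] * sin(2 * pi * profile$frequency[c] * t_sec + profile$phase[c])
  }
  out
}

#' Simulate a labeled multichannel sensor stream
#'
#' Draws a semi-Markov sequence of activity bouts (durations truncated-normal
#' with a one-sample floor, successor drawn from the transition matrix),
#' renders each bout's per-channel sinusoidal signature, blends consecutive
#' bouts with a linear cross-fade of length `transition_len_s`, and adds
#' i.i.d. Gaussian noise. Deterministic for a fixed spec (including seed).
#'
#' @param spec A [stream_spec].
#' @return An object of class `labeled_stream` with elements `values`
#'   (`T x n_channels` matrix), `labels` (length-`T` integer vector,
#'   0-based class indices; the reserved transition class is `k` when
#'   `transition_label = "reserved"`), `label_names`, `rate_hz`,
#'   `channel_names`, and `bouts` / `transitions` data frames recording the
#'   drawn segment structure (sample indices, and for transitions the
#'   flanking activity pair).
#' @export
simulate_stream <- function(spec) {
  stopifnot(inherits(spec, "stream_spec"))
  T_total <- round(spec$total_duration_s * spec$rate_hz)
  k <- spec$k
  with_seed(spec$seed, {
    # draw bout sequence until it covers the stream
    acts <- integer(0)
    lens <- integer(0)
    covered <- 0L
    cur <- sample.int(k, 1L, prob = spec$class_prior)
    while (covered < T_total) {
      p <- spec$profiles[[cur]]
      dur_s <- stats::rnorm(1, p$duration_mean, p$duration_sd)
      len <- max(1L, round(dur_s * spec$rate_hz))
      acts <- c(acts, cur)
      lens <- c(lens, len)
      covered <- covered + len
      cur <- sample.int(k, 1L, prob = spec$transition_matrix[cur, ])
    }
    lens[length(lens)] <- lens[length(lens)] - (covered - T_total)

    n_bouts <- length(acts)
    starts <- cumsum(c(1L, lens[-n_bouts]))
    ends <- cumsum(lens)
    t_all <- (seq_len(T_total) - 1L) / spec$rate_hz

    values <- matrix(0, T_total, spec$n_channels)
    labels <- integer(T_total)
    for (b in seq_len(n_bouts)) {
      idx <- starts[b]:ends[b]
      values[idx, ] <- signature_block(spec$profiles[[acts[b]]], t_all[idx])
      labels[idx] <- acts[b] - 1L
    }

    # linear cross-fade centered on each bout boundary
    fade_len <- round(spec$transition_len_s * spec$rate_hz)
    transitions <- NULL
    if (fade_len > 0L && n_bouts > 1L) {
      rec <- vector("list", n_bouts - 1L)
      for (b in seq_len(n_bouts - 1L)) {
        boundary <- ends[b]
        lo <- max(1L, boundary - floor(fade_len / 2) + 1L)
        hi <- min(T_total, lo + fade_len - 1L)
        idx <- lo:hi
        w <- seq_along(idx) / (length(idx) + 1L)  # weight of incoming activity
        sig_from <- signature_block(spec$profiles[[acts[b]]], t_all[idx])
        sig_to <- signature_block(spec$profiles[[acts[b + 1L]]], t_all[idx])
        values[idx, ] <- (1 - w) * sig_from + w * sig_to
        labels[idx] <- if (spec$transition_label == "reserved") k else acts[b + 1L] - 1L
        rec[[b]] <- data.frame(
          start = lo, end = hi,
          from = acts[b] - 1L, to = acts[b + 1L] - 1L
        )
      }
      transitions <- do.call(rbind, rec)
    }

    if (spec$noise_sd > 0) {
      values <- values + matrix(
        stats::rnorm(length(values), 0, spec$noise_sd),
        nrow(values), ncol(values)
      )
    }

    label_names <- vapply(spec$profiles, `[[`, character(1), "name")
    if (spec$transition_label == "reserved") label_names <- c(label_names, "TRANS")
    channel_names <- if (spec$n_channels == 9L) DEFAULT_CHANNELS
                     else sprintf("ch%02d", seq_len(spec$n_channels))
    structure(
      list(
        values = values, labels = labels, rate_hz = spec$rate_hz,
        label_names = label_names, channel_names = channel_names,
        bouts = data.frame(activity = acts - 1L, start = starts, end = ends),
        transitions = transitions, spec = spec
      ),
      class = "labeled_stream"
    )
  })
}

#' @export
print.labeled_stream <- function(x, ...) {
  cat(sprintf(
    "<labeled_stream> %d samples x %d channels @ %g Hz, %d activity labels\n",
    nrow(x$values), ncol(x$values), x$rate_hz, length(x$label_names)
  ))
  invisible(x)
}

#' Flanking activity pair for each window of a segmented stream
#'
#' For windows cut from a simulated stream with reserved transition labels,
#' returns the `(from, to)` activity pair of the cross-fade each window
#' overlaps most (NA for windows that touch no transition). Used to check
#' that transition windows embed between their flanking activities.
#'
#' @param stream A [simulate_stream()] result (needs its `transitions`
#'   table).
#' @param ws The [window_set] segmented from that stream.
#' @return Two-column integer matrix (`from`, `to`), one row per window.
#' @export
window_transition_flanks <- function(stream, ws) {
  n_win <- dim(ws$tensor)[1L]
  out <- matrix(NA_integer_, n_win, 2L, dimnames = list(NULL, c("from", "to")))
  tr <- stream$transitions
  if (is.null(tr) || nrow(tr) == 0L) return(out)
  for (w in seq_len(n_win)) {
    lo <- (w - 1L) * ws$step + 1L
    hi <- lo + ws$window_len - 1L
    ov <- pmin(hi, tr$end) - pmax(lo, tr$start) + 1L
    best <- which.max(ov)
    if (ov[best] > 0L) out[w, ] <- c(tr$from[best], tr$to[best])
  }
  out
}

#' Write a labeled stream as a MobiAct-dialect CSV file
#'
#' Columns: `timestamp` (ISO-8601), `rel_time` (seconds), the nine sensor
#' channels, and the activity `label` string. Values are printed with enough
#' significant digits for a lossless round trip through
#' [read_mobiact_csv()].
#'
#' @param stream A `labeled_stream` (or any list with `values`, `labels`,
#'   `label_names`, `channel_names`, `rate_hz`).
#' @param path Output file path.
#' @param origin POSIXct origin for the timestamp column.
#' @return `path`, invisibly.
#' @export
write_stream_csv <- function(stream, path,
                             origin = as.POSIXct("2026-01-01 00:00:00", tz = "UTC")) {
  T_n <- nrow(stream$values)
  rel_time <- if (T_n > 0L) (seq_len(T_n) - 1L) / stream$rate_hz else numeric(0)
  df <- data.frame(
    timestamp = format(origin + rel_time, "%Y-%m-%dT%H:%M:%OS6Z"),
    rel_time = rel_time,
    check.names = FALSE
  )
  vals <- as.data.frame(stream$values)
  names(vals) <- stream$channel_names
  df <- cbind(df, vals)
  df$label <- stream$label_names[stream$labels + 1L]
  if (T_n == 0L) df <- df[0L, , drop = FALSE]
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_bad_arg("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  old <- options(digits = 15)
  on.exit(options(old), add = TRUE)
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
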