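# Readers and preprocessing: MobiAct-dialect CSV, UCI-HAR raw-signal
# directories, MinMax scaling, sliding-window segmentation.

DEFAULT_CHANNELS <- c(
  "acc_x", "acc_y", "acc_z",
  "gyro_x", "gyro_y", "gyro_z",
  "azimuth", "pitch", "roll"
)

MOBIACT_COLUMNS <- c("timestamp", "rel_time", DEFAULT_CHANNELS, "label")

new_sensor_frame <- function(values, labels, label_names, channel_names, rate_hz) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop_bad_arg("sensor frame must have at least one sample")
  if (anyNA(values)) stop_bad_arg("sensor frame contains missing values")
  if (length(labels) != nrow(values))
    stop_bad_arg("labels length (%d) != number of samples (%d)",
                 length(labels), nrow(values))
  structure(
    list(
      values = values, labels = as.integer(labels),
      label_names = label_names, channel_names = channel_names,
      rate_hz = rate_hz
    ),
    class = "sensor_frame"
  )
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat(sprintf(
    "<sensor_frame> %d samples x %d channels @ %g Hz; classes: %s\n",
    nrow(x$values), ncol(x$values), x$rate_hz,
    paste(x$label_names, collapse = ", ")
  ))
  invisible(x)
}

#' Read a MobiAct-dialect CSV recording
#'
#' Expects the 12-column layout (`timestamp`, `rel_time`, accelerometer
#' x/y/z, gyroscope x/y/z, azimuth, pitch, roll, `label`). The metadata
#' columns `timestamp` and `rel_time` are dropped — only sensor readings
#' feed the models — and the label strings are integer-encoded with a name
#' table. Unknown extra columns are ignored with a warning; a missing
#' required column is a format error naming the column.
#'
#' @param path CSV file path.
#' @param rate_hz Sampling rate to record on the frame (default 200). When
#'   the file has at least two rows the rate is inferred from `rel_time`.
#' @return A `sensor_frame`.
#' @export
read_mobiact_csv <- function(path, rate_hz = 200) {
  if (!file.exists(path)) stop_bad_arg("file not found: '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(MOBIACT_COLUMNS, names(df))
  if (length(missing) > 0L)
    stop_bad_arg("malformed MobiAct CSV '%s': missing column(s) %s",
                 path, paste(sprintf("'%s'", missing), collapse = ", "))
  extra <- setdiff(names(df), MOBIACT_COLUMNS)
  if (length(extra) > 0L)
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  if (nrow(df) >= 2L) {
    dt <- diff(as.numeric(df$rel_time))
    dt <- dt[dt > 0]
    if (length(dt) > 0L) rate_hz <- 1 / stats::median(dt)
  }
  values <- as.matrix(df[, DEFAULT_CHANNELS, drop = FALSE])
  storage.mode(values) <- "double"
  if (anyNA(values)) {
    keep <- stats::complete.cases(values)
    warning(sprintf("dropping %d row(s) with missing sensor values",
                    sum(!keep)), call. = FALSE)
    values <- values[keep, , drop = FALSE]
    df <- df[keep, , drop = FALSE]
  }
  label_names <- sort(unique(as.character(df$label)))
  labels <- match(as.character(df$label), label_names) - 1L
  new_sensor_frame(values, labels, label_names, DEFAULT_CHANNELS, rate_hz)
}

#' Read a UCI-HAR style raw-signal directory
#'
#' Expects the benchmark layout for one split: an `Inertial Signals/`
#' subdirectory holding nine whitespace-delimited files (`<signal>_<split>.txt`,
#' one pre-segmented 128-sample window per row) plus `y_<split>.txt` with one
#' activity label (1..6) per window. Windows come pre-segmented at 2.56 s /
#' 50% overlap by the dataset authors, so the result is a [window_set]
#' directly.
#'
#' @param path Split directory (e.g. `.../UCI HAR Dataset/train`).
#' @param split `"train"` or `"test"` (used in the file names).
#' @return A `window_set` with `window_len = 128` and 9 channels; labels are
#'   re-indexed to 0..5.
#' @export
read_uci_har_dir <- function(path, split = c("train", "test")) {
  split <- match.arg(split)
  signals <- c(
    "body_acc_x", "body_acc_y", "body_acc_z",
    "body_gyro_x", "body_gyro_y", "body_gyro_z",
    "total_acc_x", "total_acc_y", "total_acc_z"
  )
  sig_dir <- file.path(path, "Inertial Signals")
  if (!dir.exists(sig_dir)) stop_bad_arg("no 'Inertial Signals' directory under '%s'", path)
  mats <- lapply(signals, function(s) {
    f <- file.path(sig_dir, sprintf("%s_%s.txt", s, split))
    if (!file.exists(f)) stop_bad_arg("missing signal file '%s'", f)
    as.matrix(utils::read.table(f))
  })
  n_rows <- vapply(mats, nrow, integer(1))
  n_cols <- vapply(mats, ncol, integer(1))
  if (length(unique(n_rows)) != 1L || length(unique(n_cols)) != 1L)
    stop_bad_arg("signal files disagree on shape (rows %s, cols %s)",
                 paste(unique(n_rows), collapse = "/"),
                 paste(unique(n_cols), collapse = "/"))
  if (unique(n_cols) != 128L)
    stop_bad_arg("expected 128 readings per window, found %d", unique(n_cols))
  y_file <- file.path(path, sprintf("y_%s.txt", split))
  if (!file.exists(y_file)) stop_bad_arg("missing label file '%s'", y_file)
  y <- utils::read.table(y_file)[[1L]]
  if (length(y) != unique(n_rows))
    stop_bad_arg("label count (%d) != window count (%d)", length(y), unique(n_rows))
  if (!all(y %in% 1:6))
    stop_bad_arg("labels outside 1..6 found in '%s'", y_file)
  n <- unique(n_rows)
  tensor <- array(0, c(n, 128L, 9L))
  for (c in seq_along(mats)) tensor[, , c] <- mats[[c]]
  uci_names <- c("WALKING", "WALKING_UPSTAIRS", "WALKING_DOWNSTAIRS",
                 "SITTING", "STANDING", "LAYING")
  window_set(tensor, as.integer(y) - 1L, window_len = 128L, step = 64L,
             label_names = uci_names, channel_names = signals,
             provenance = normalizePath(path, mustWork = FALSE))
}

# MinMax scaler ---------------------------------------------------------------

#' Fit a per-channel MinMax scaler
#'
#' Records each channel's min and max on the supplied frame so that
#' [apply_scaler()] maps that range linearly onto `target_range`. Fit the
#' scaler on the training split only to avoid leaking test statistics (the
#' whole-dataset variant is just fitting on the full frame).
#'
#' @param frame A `sensor_frame`.
#' @param target_range Length-2 numeric `(lo, hi)`; `(0, 1)` suits
#'   sigmoid-output autoencoders, `(-1, 1)` suits streaming discriminators.
#' @return An object of class `minmax_scaler`.
#' @export
fit_scaler <- function(frame, target_range = c(0, 1)) {
  stopifnot(is.numeric(target_range), length(target_range) == 2L,
            target_range[2] > target_range[1])
  v <- frame$values
  structure(
    list(
      per_channel_min = apply(v, 2, min),
      per_channel_max = apply(v, 2, max),
      target_range = as.numeric(target_range)
    ),
    class = "minmax_scaler"
  )
}

#' Apply a fitted MinMax scaler to a sensor frame
#'
#' `x' = lo + (x - min) * (hi - lo) / (max - min)` per channel. A constant
#' channel (`max == min`) maps to `lo`. Values outside the fitted range
#' extrapolate linearly (and are clipped to the target range only by
#' downstream consumers that require it).
#'
#' @param frame A `sensor_frame`.
#' @param scaler A `minmax_scaler` from [fit_scaler()].
#' @return A rescaled `sensor_frame`.
#' @export
apply_scaler <- function(frame, scaler) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  lo <- scaler$target_range[1]; hi <- scaler$target_range[2]
  rng <- scaler$per_channel_max - scaler$per_channel_min
  v <- frame$values
  out <- matrix(lo, nrow(v), ncol(v))
  ok <- rng > 0
  if (any(ok)) {
    out[, ok] <- sweep(v[, ok, drop = FALSE], 2, scaler$per_channel_min[ok]) %*%
      diag((hi - lo) / rng[ok], sum(ok)) + lo
  }
  frame$values <- out
  frame
}

# Window sets -----------------------------------------------------------------

#' Construct a window set
#'
#' The tensor of fixed-length sensor windows consumed by every feature
#' extractor: `n_windows x window_len x n_channels`, one label per window.
#'
#' @param tensor 3-D numeric array `[n_windows, window_len, n_channels]`.
#' @param window_labels Integer vector (0-based class indices).
#' @param window_len,step Segmentation geometry (samples).
#' @param label_names,channel_names Optional name tables.
#' @param provenance Free-form source identifier(s).
#' @return An object of class `window_set`.
#' @export
window_set <- function(tensor, window_labels, window_len = dim(tensor)[2],
                       step = window_len, label_names = NULL,
                       channel_names = NULL, provenance = "in-memory") {
  stopifnot(is.array(tensor), length(dim(tensor)) == 3L)
  if (length(window_labels) != dim(tensor)[1L])
    stop_bad_arg("one label per window required")
  window_len <- check_count(window_len, "window_len")
  step <- check_count(step, "step")
  if (step > window_len) stop_bad_arg("`step` must be <= `window_len`")
  structure(
    list(
      tensor = tensor, window_labels = as.integer(window_labels),
      window_len = window_len, step = step,
      label_names = label_names, channel_names = channel_names,
      provenance = provenance
    ),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf(
    "<window_set> %d windows of %d samples x %d channels (step %d)\n",
    d[1], d[2], d[3], x$step
  ))
  cat("  class counts:",
      paste(sprintf("%s=%d", names(table(x$window_labels)), table(x$window_labels)),
            collapse = " "), "\n")
  invisible(x)
}

#' Segment a continuous stream into fixed-length windows
#'
#' Sliding-window segmentation: `step = round(window_len * (1 - overlap_frac))`
#' (floored at 1), `n_windows = floor((T - window_len) / step) + 1`; any
#' trailing partial window is discarded. Each window's label is the majority
#' label of its samples, ties broken by the label of the window's last
#' sample.
#'
#' @param frame A `sensor_frame` or `labeled_stream`.
#' @param window_len Window length in samples (e.g. 200 for 1 s at 200 Hz).
#' @param overlap_frac Fractional overlap of consecutive windows in `[0, 1)`;
#'   `0.5` gives 50% overlap.
#' @return A [window_set].
#' @export
segment_windows <- function(frame, window_len, overlap_frac = 0) {
  window_len <- check_count(window_len, "window_len")
  check_number(overlap_frac, "overlap_frac", lower = 0, upper = 1 - 1e-12)
  v <- frame$values
  T_n <- nrow(v)
  if (window_len > T_n)
    stop_bad_arg("`window_len` (%d) exceeds stream length (%d)", window_len, T_n)
  step <- max(1L, as.integer(round(window_len * (1 - overlap_frac))))
  n_win <- (T_n - window_len) %/% step + 1L
  tensor <- array(0, c(n_win, window_len, ncol(v)))
  labels <- integer(n_win)
  for (w in seq_len(n_win)) {
    idx <- (w - 1L) * step + seq_len(window_len)
    tensor[w, , ] <- v[idx, ]
    lab <- frame$labels[idx]
    tab <- table(lab)
    top <- as.integer(names(tab)[tab == max(tab)])
    labels[w] <- if (length(top) == 1L) top else lab[length(lab)]
  }
  window_set(tensor, labels, window_len = window_len, step = step,
             label_names = frame$label_names,
             channel_names = frame$channel_names,
             provenance = "segment_windows")
}
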