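#' Construct a single-channel time series
#'
#' A `time_series` is a raw or normalized single-channel recording together
#' with its sampling rate. All downstream stages (normalization, epoching,
#' visibility graphs) operate on this container or on plain numeric vectors.
#'
#' @param samples Numeric vector of samples (arbitrary units). Must be
#'   non-empty and finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_id Optional text label for the channel.
#' @return An object of class `time_series`: a numeric vector with
#'   `sampling_rate` and `channel_id` attributes.
#' @examples
#' x <- time_series(sin(seq(0, 1, length.out = 100)), sampling_rate = 100)
#' range(normalize_recording(x))
#' @export
time_series <- function(samples, sampling_rate, channel_id = "ch1") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("'samples' must be non-empty", call. = FALSE)
  }
  bad <- which(!is.finite(samples))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite sample at index %d", bad[1L]), call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("'sampling_rate' must be a single positive number (Hz)", call. = FALSE)
  }
  structure(samples,
            sampling_rate = as.numeric(sampling_rate),
            channel_id = as.character(channel_id),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> channel '%s': %d samples @ %.6g Hz (%.4g s)\n",
              attr(x, "channel_id"), length(x),
              attr(x, "sampling_rate"),
              length(x) / attr(x, "sampling_rate")))
  invisible(x)
}

# Accept a time_series or bare numeric vector; return the numeric payload.
as_samples <- function(x) {
  if (inherits(x, "time_series")) as.numeric(unclass(x)) else as.numeric(x)
}

#' Scale a recording to the unit interval
#'
#' Applies min-max normalization referenced to the full-recording extrema:
#' `(x - min(x)) / (max(x) - min(x))`. A constant recording maps to all
#' zeros rather than erroring, so downstream graph construction has a
#' defined (chain-shaped) result. Normalization against the whole recording
#' -- not per epoch -- preserves between-epoch amplitude relationships,
#' which the Gershgorin features rely on.
#'
#' @param x A [time_series] or numeric vector with finite values.
#' @return Object of the same type with samples in `[0, 1]`.
#' @examples
#' normalize_recording(c(2, 4, 6))  # 0.0 0.5 1.0
#' @export
normalize_recording <- function(x) {
  s <- as_samples(x)
  if (length(s) == 0L) stop("empty recording", call. = FALSE)
  bad <- which(!is.finite(s))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite sample at index %d", bad[1L]), call. = FALSE)
  }
  lo <- min(s)
  hi <- max(s)
  out <- if (hi > lo) (s - lo) / (hi - lo) else rep(0, length(s))
  if (inherits(x, "time_series")) {
    time_series(out, attr(x, "sampling_rate"), attr(x, "channel_id"))
  } else {
    out
  }
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the recording into `floor(length / N)` consecutive, non-overlapping
#' windows of `N` samples, preserving time order. A trailing remainder
#' shorter than `N` is discarded (padding would fabricate visibility edges).
#'
#' @param x A [time_series] or numeric vector, usually already normalized
#'   with [normalize_recording()].
#' @param N Epoch length in samples (>= 2).
#' @param labels Optional integer class label, either length 1 (recycled)
#'   or one per resulting epoch.
#' @param per_epoch_normalize If `TRUE`, each epoch is re-scaled to `[0, 1]`
#'   against its own extrema. Off by default: the recording-level extrema
#'   are the reference of record, but users who only have isolated windows
#'   may lack that context.
#' @return An `epoch_set`: a numeric matrix with one epoch per row and
#'   attributes `epoch_index` (1-based position in the recording) and
#'   `label` (integer vector or `NULL`).
#' @examples
#' es <- segment_epochs(runif(4096), 1024)
#' nrow(es)  # 4
#' @export
segment_epochs <- function(x, N, labels = NULL, per_epoch_normalize = FALSE) {
  s <- as_samples(x)
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("'N' must be an integer >= 2", call. = FALSE)
  if (length(s) < N) stop("recording shorter than epoch", call. = FALSE)
  k <- length(s) %/% N
  m <- matrix(s[seq_len(k * N)], nrow = k, ncol = N, byrow = TRUE)
  if (per_epoch_normalize) {
    m <- t(apply(m, 1L, function(q) {
      lo <- min(q); hi <- max(q)
      if (hi > lo) (q - lo) / (hi - lo) else rep(0, length(q))
    }))
  }
  epoch_set(m, labels = labels)
}

#' Assemble an epoch matrix into an `epoch_set`
#'
#' @param m Numeric matrix, one epoch per row.
#' @param labels Optional integer labels (length 1 or `nrow(m)`).
#' @param epoch_index Optional integer positions; defaults to `1:nrow(m)`.
#' @return The matrix with class `epoch_set` and `epoch_index` / `label`
#'   attributes.
#' @export
epoch_set <- function(m, labels = NULL, epoch_index = NULL) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("epochs must have at least 2 samples", call. = FALSE)
  if (is.null(epoch_index)) epoch_index <- seq_len(nrow(m))
  if (!is.null(labels)) {
    if (length(labels) == 1L) labels <- rep(as.integer(labels), nrow(m))
    if (length(labels) != nrow(m)) {
      stop("'labels' must have one entry per epoch", call. = FALSE)
    }
    labels <- as.integer(labels)
  }
  structure(m,
            epoch_index = as.integer(epoch_index),
            label = labels,
            class = c("epoch_set", "matrix", "array"))
}

#' @export
print.epoch_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<epoch_set> %d epochs x %d samples", nrow(x), ncol(x)))
  if (!is.null(lab)) {
    tab <- table(lab)
    cat("; labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' @export
`[.epoch_set` <- function(x, i, ...) {
  m <- unclass(x)
  attr(m, "epoch_index") <- NULL
  attr(m, "label") <- NULL
  class(m) <- NULL
  out <- m[i, , drop = FALSE]
  epoch_set(out,
            labels = if (!is.null(attr(x, "label"))) attr(x, "label")[i],
            epoch_index = attr(x, "epoch_index")[i])
}

#' Read a single-channel recording from delimited text
#'
#' Supports the two plain-text layouts the pipeline exchanges: one sample
#' per line, or CSV with one channel per column (optionally with a header).
#' The sampling rate is never inferred from the file; it must be supplied.
#'
#' @param path Path to the file.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel For CSV input, the column name or index to read
#'   (default 1).
#' @param header Does the CSV have a header row? Ignored for single-column
#'   files without separators.
#' @return A [time_series].
#' @export
read_recording <- function(path, sampling_rate, channel = 1L, header = NA) {
  first <- readLines(path, n = 1L)
  if (grepl("[,\t;]", first)) {
    if (is.na(header)) {
      header <- !grepl("^[-+0-9.eE,\t; ]+$", first)
    }
    df <- utils::read.csv(path, header = header)
    col <- df[[channel]]
    id <- if (is.character(channel)) channel else names(df)[channel]
  } else {
    vals <- scan(path, what = numeric(), quiet = TRUE,
                 comment.char = "#")
    col <- vals
    id <- "ch1"
  }
  time_series(col, sampling_rate, channel_id = id)
}

#' Write an epoch set as CSV
#'
#' One epoch per row with an `epoch_index` column and, when labels are
#' present, a `label` column, followed by the sample columns `s1..sN`.
#'
#' @param epochs An `epoch_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epochs_csv <- function(epochs, path) {
  m <- unclass(epochs)
  df <- as.data.frame(m)
  names(df) <- paste0("s", seq_len(ncol(m)))
  df <- cbind(epoch_index = attr(epochs, "epoch_index"), df)
  lab <- attr(epochs, "label")
  if (!is.null(lab)) df <- cbind(df[1L], label = lab, df[-1L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an epoch set written by [write_epochs_csv()]
#'
#' @param path CSV path.
#' @return An `epoch_set`.
#' @export
read_epochs_csv <- function(path) {
  df <- utils::read.csv(path)
  lab <- if ("label" %in% names(df)) as.integer(df$label) else NULL
  idx <- if ("epoch_index" %in% names(df)) as.integer(df$epoch_index) else NULL
  keep <- grepl("^s[0-9]+$", names(df))
  epoch_set(as.matrix(df[keep]), labels = lab, epoch_index = idx)
}
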