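#' Partition a stream into fixed-duration windows
#'
#' Non-overlapping sliding-window segmentation: the stream is tiled into
#' consecutive segments of `floor(window_seconds * sampling_rate)` samples;
#' a trailing partial window is discarded. Each window carries its sample
#' index range (half-open, zero-based), its end time in seconds, the
#' majority activity label, the label purity (fraction of rows carrying the
#' majority label) and a transition flag (`purity < 1`). A majority tie is
#' broken toward the tied label occurring earliest in the window, so a tie
#' involving the first row's label resolves to it. An optional `stride`
#' (in samples) gives overlapping windows; the default stride equals the
#' window length, which is the configuration the recognition model uses.
#'
#' @param matrix A [channel_matrix()].
#' @param window_seconds Window duration in seconds; the recognition model
#'   uses 2 s, i.e. 100 samples at 50 Hz.
#' @param stride Hop in samples between window starts; default = window
#'   length (non-overlapping).
#' @return List of `har_window` objects (empty for an empty matrix).
#' @export
make_windows <- function(matrix, window_seconds = 2, stride = NULL) {
  stopifnot(inherits(matrix, "channel_matrix"))
  fs <- matrix$sampling_rate
  n <- floor(window_seconds * fs)
  if (n < 1L) stop("window shorter than one sample")
  n <- as.integer(n)
  if (is.null(stride)) stride <- n
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  nr <- nrow(matrix$values)
  if (nr < n) return(list())
  starts <- seq(0L, nr - n, by = stride)
  lapply(starts, function(s) {
    rows <- (s + 1L):(s + n)
    new_window(matrix$values[rows, , drop = FALSE],
               matrix$labels[rows], s, s + n, fs)
  })
}

new_window <- function(values, labels, start_index, end_index, fs) {
  maj <- majority_label(labels)
  structure(list(values = values,
                 start_index = as.integer(start_index),
                 end_index = as.integer(end_index),
                 end_time = end_index / fs,
                 label = maj$label,
                 purity = maj$purity,
                 is_transition = maj$purity < 1),
            class = "har_window")
}

# majority with ties broken toward the earliest-occurring tied label
majority_label <- function(labels) {
  u <- unique(labels)                     # first-occurrence order
  cnt <- tabulate(match(labels, u))
  i <- which.max(cnt)                     # first maximum = earliest label
  list(label = u[i], purity = cnt[i] / length(labels))
}

#' @export
print.har_window <- function(x, ...) {
  cat(sprintf(
    "<har_window> rows [%d,%d) end %.2fs label %d purity %.2f%s\n",
    x$start_index, x$end_index, x$end_time, x$label, x$purity,
    if (x$is_transition) " (transition)" else ""))
  invisible(x)
}

#' Streaming window buffer
#'
#' Runtime counterpart of [make_windows()]: create a buffer with
#' `har_stream()`, then feed samples one at a time with [stream_push()]. A
#' window is emitted exactly when the n-th buffered sample arrives, after
#' which the buffer resets; the sequence of emitted windows is bitwise
#' identical to batch segmentation of the concatenated stream.
#'
#' @param window_seconds Window duration in seconds.
#' @param channels Character vector of channel names expected per sample.
#' @param sampling_rate Hz.
#' @return An object of class `har_stream`.
#' @export
har_stream <- function(window_seconds, channels, sampling_rate) {
  n <- floor(window_seconds * sampling_rate)
  if (n < 1L) stop("window shorter than one sample")
  e <- new.env(parent = emptyenv())
  e$n <- as.integer(n)
  e$channels <- channels
  e$fs <- sampling_rate
  e$buf <- matrix(NA_real_, n, length(channels),
                  dimnames = list(NULL, channels))
  e$labels <- integer(n)
  e$count <- 0L
  e$total <- 0L
  class(e) <- "har_stream"
  e
}

#' @param state A [har_stream()] buffer.
#' @param values Numeric vector, one value per declared channel.
#' @param label Integer activity label of the sample.
#' @return The completed `har_window` when the buffer fills, else `NULL`
#'   (invisibly).
#' @rdname har_stream
#' @export
stream_push <- function(state, values, label = 0L) {
  stopifnot(inherits(state, "har_stream"))
  if (length(values) != length(state$channels))
    stop(sprintf("sample has %d values but the stream declares %d channels",
                 length(values), length(state$channels)))
  state$count <- state$count + 1L
  state$total <- state$total + 1L
  state$buf[state$count, ] <- as.numeric(values)
  state$labels[state$count] <- as.integer(label)
  if (state$count < state$n) return(invisible(NULL))
  w <- new_window(state$buf, state$labels,
                  state$total - state$n, state$total, state$fs)
  state$count <- 0L
  w
}

#' Segmentation delay of a window-end prediction
#'
#' A prediction produced at the end of a window refers, on average, to the
#' temporal centre of that window, so aligning predictions with ground truth
#' requires shifting by half the window length — 1 s for the 2-s windows of
#' the recognition model.
#'
#' @param window_seconds Window duration in seconds (positive).
#' @return Delay in seconds (`window_seconds / 2`).
#' @export
segmentation_delay <- function(window_seconds) {
  if (!is.numeric(window_seconds) || window_seconds <= 0)
    stop("window_seconds must be positive")
  window_seconds / 2
}
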