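#' Sampling-rate adjustment
#'
#' The two rate-conversion techniques the pipeline supports: `downsample()`
#' keeps every `factor`-th row (plain decimation, no anti-alias filter —
#' deterministic and adequate for the label-aligned streams handled here);
#' `upsample()` inserts `factor - 1` linearly interpolated rows between each
#' consecutive pair. Labels are decimated identically on the way down and
#' copied from the left neighbour on the way up, so no label value ever
#' appears that was absent from the input. Rational rate conversion is
#' obtained by composing the two.
#'
#' `downsample(upsample(x, k), k)` recovers `x` exactly: interpolation at the
#' original grid points returns the original rows.
#'
#' @param matrix A [channel_matrix()].
#' @param factor Positive integer rate factor.
#' @return A [channel_matrix()] at the adjusted rate.
#' @export
downsample <- function(matrix, factor) {
  stopifnot(inherits(matrix, "channel_matrix"))
  check_factor(factor)
  if (nrow(matrix$values) == 0L) stop("matrix must be non-empty")
  idx <- seq(1L, nrow(matrix$values), by = factor)
  channel_matrix(matrix$values[idx, , drop = FALSE], matrix$labels[idx],
                 matrix$sampling_rate / factor)
}

#' @rdname downsample
#' @export
upsample <- function(matrix, factor) {
  stopifnot(inherits(matrix, "channel_matrix"))
  check_factor(factor)
  n <- nrow(matrix$values)
  if (factor == 1L) return(matrix)
  if (n < 2L) stop("upsampling needs at least 2 rows")
  xout <- seq(1, n, by = 1 / factor)
  vals <- apply(matrix$values, 2L, function(col) {
    stats::approx(seq_len(n), col, xout = xout, method = "linear")$y
  })
  # exact originals at the knots so decimation inverts interpolation
  orig_at <- (seq_along(xout) - 1L) %% factor == 0L
  vals[orig_at, ] <- matrix$values
  colnames(vals) <- matrix$channel_names
  channel_matrix(vals, matrix$labels[floor(xout)],
                 matrix$sampling_rate * factor)
}

check_factor <- function(factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("factor must be a positive integer")
  invisible(as.integer(factor))
}
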