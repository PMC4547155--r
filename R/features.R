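#' Time-domain window statistics
#'
#' The per-channel statistics available for feature extraction: `mean`,
#' `variance` (sample variance, N-1 denominator), `std`, `max`, `min`,
#' `zcr` (zero-crossing rate) and `mcr` (mean-crossing rate).
#'
#' `zcr` counts sign changes between consecutive samples. A zero sample
#' inherits the most recent nonzero sign; leading zeros count as positive.
#' It is a count of transitions within the window, not normalised by the
#' window length. `mcr` is `zcr` applied to the mean-centred signal, so the
#' mean-crossing count of any constant window is 0.
#'
#' @param x Non-empty numeric vector (variance/std need at least 2 samples).
#' @param statistic One of `"mean"`, `"variance"`, `"std"`, `"max"`,
#'   `"min"`, `"zcr"`, `"mcr"`.
#' @return A single number.
#' @export
window_statistic <- function(x, statistic = c("mean", "variance", "std",
                                              "max", "min", "zcr", "mcr")) {
  statistic <- match.arg(statistic)
  if (length(x) == 0L) stop("x must be non-empty")
  if (statistic %in% c("variance", "std") && length(x) < 2L)
    stop(sprintf("%s needs at least 2 samples", statistic))
  switch(statistic,
         mean = mean(x),
         variance = stats::var(x),
         std = stats::sd(x),
         max = max(x),
         min = min(x),
         zcr = sign_changes(x),
         mcr = sign_changes(x - mean(x)))
}

# sign changes with zero inheriting the last nonzero sign (leading zeros +)
sign_changes <- function(x) {
  s <- sign(x)
  nz <- s != 0
  filled <- c(1, s[nz])[cumsum(nz) + 1L]
  sum(diff(filled) != 0)
}

#' Statistics the recognition model uses by default
#'
#' Mean, standard deviation, maximum and minimum — on the nine acceleration
#' channels these give the 36-dimensional feature vector of the recognition
#' model. The remaining statistics ([window_statistic()]) stay available to
#' library users.
#'
#' @return Character vector of statistic names.
#' @export
default_statistics <- function() c("mean", "std", "max", "min")

#' Extract a feature matrix from segmented windows
#'
#' One row per window; columns ordered with channels as the outer loop and
#' statistics as the inner loop, named `"channel:statistic"`. Window labels
#' and end times are carried along.
#'
#' @param windows List of windows from [make_windows()] (shared layout).
#' @param channels Channels to use; default all columns of the windows.
#' @param statistics Non-empty subset of the available statistics; default
#'   [default_statistics()].
#' @return An object of class `feature_matrix` with fields `values`
#'   (windows x features), `feature_names`, `labels`, `end_times`.
#' @export
extract_features <- function(windows, channels = NULL,
                             statistics = default_statistics()) {
  if (length(statistics) == 0L) stop("statistics must be non-empty")
  valid <- c("mean", "variance", "std", "max", "min", "zcr", "mcr")
  bad <- setdiff(statistics, valid)
  if (length(bad))
    stop(sprintf("unknown statistic(s): %s", paste(bad, collapse = ", ")))
  if (length(windows) == 0L) stop("no windows to extract features from")
  if (is.null(channels)) channels <- colnames(windows[[1L]]$values)
  fnames <- as.vector(t(outer(channels, statistics, paste, sep = ":")))
  vals <- t(vapply(windows, function(w) {
    missing <- setdiff(channels, colnames(w$values))
    if (length(missing))
      stop(sprintf("window lacks channel(s): %s",
                   paste(missing, collapse = ", ")))
    unlist(lapply(channels, function(ch) {
      vapply(statistics, function(s) window_statistic(w$values[, ch], s),
             numeric(1))
    }), use.names = FALSE)
  }, numeric(length(fnames))))
  if (length(windows) == 1L) vals <- matrix(vals, nrow = 1L)
  colnames(vals) <- fnames
  structure(list(values = vals, feature_names = fnames,
                 labels = vapply(windows, function(w) w$label, integer(1)),
                 end_times = vapply(windows, function(w) w$end_time,
                                    numeric(1))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$labels)
  cat("  windows per label:",
      paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Read and write feature matrices as headered CSV
#'
#' Columns are the feature names plus a final `label` column (and an
#' `end_time` column when available).
#'
#' @param features A [extract_features()] result.
#' @param path CSV path.
#' @return `write_features_csv()`: `path`, invisibly;
#'   `read_features_csv()`: a `feature_matrix`.
#' @export
write_features_csv <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  df <- as.data.frame(features$values, check.names = FALSE)
  df$label <- features$labels
  df$end_time <- features$end_times
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("feature CSV lacks a label column")
  labels <- as.integer(df$label)
  end_times <- if ("end_time" %in% names(df)) as.numeric(df$end_time) else
    rep(NA_real_, nrow(df))
  keep <- setdiff(names(df), c("label", "end_time"))
  vals <- as.matrix(df[, keep, drop = FALSE])
  structure(list(values = vals, feature_names = keep,
                 labels = labels, end_times = end_times),
            class = "feature_matrix")
}
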