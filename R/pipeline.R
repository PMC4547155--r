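#' Session to recognition features
#'
#' The standard front half of the recognition pipeline: select the nine
#' acceleration channels, segment into non-overlapping windows (default
#' 2 s) and extract the default statistics (mean, std, max, min), giving
#' the 36-dimensional feature vector per window.
#'
#' @param session A [har_session()].
#' @param window_seconds Window duration in seconds.
#' @param channels Channels to use; default [acceleration_channels()].
#' @param statistics Statistics; default [default_statistics()].
#' @param drop_transitions Drop windows with mixed or null labels before
#'   returning (default `FALSE`).
#' @return A `feature_matrix`.
#' @export
har_features <- function(session, window_seconds = 2,
                         channels = acceleration_channels(),
                         statistics = default_statistics(),
                         drop_transitions = FALSE) {
  cm <- select_channels(session, channels)
  windows <- make_windows(cm, window_seconds)
  if (drop_transitions)
    windows <- Filter(function(w) !w$is_transition && w$label != 0L,
                      windows)
  extract_features(windows, channels = channels, statistics = statistics)
}

#' Pool feature matrices from several sessions
#'
#' @param feature_list List of `feature_matrix` objects with identical
#'   feature names.
#' @return One pooled `feature_matrix`.
#' @export
bind_features <- function(feature_list) {
  stopifnot(length(feature_list) >= 1L)
  nm <- feature_list[[1L]]$feature_names
  for (f in feature_list)
    if (!identical(f$feature_names, nm))
      stop("feature matrices have differing feature names")
  structure(list(
    values = do.call(rbind, lapply(feature_list, `[[`, "values")),
    feature_names = nm,
    labels = unlist(lapply(feature_list, `[[`, "labels")),
    end_times = unlist(lapply(feature_list, `[[`, "end_times"))),
    class = "feature_matrix")
}

#' Replay a session through the streaming recognizer
#'
#' Feeds the session sample by sample into a [har_stream()] buffer; each
#' time a window completes, its features are extracted and classified,
#' yielding a timestamped prediction stream — exactly what a runtime
#' recognizer emits. The predictions equal batch classification of
#' [make_windows()] output on the same data.
#'
#' @param session A [har_session()].
#' @param model A [har_train()] model.
#' @param window_seconds Window duration in seconds.
#' @param channels,statistics Feature configuration; must match how the
#'   model was trained.
#' @return Data frame with columns `end_time` (s) and `label` (predicted).
#' @export
har_recognize <- function(session, model, window_seconds = 2,
                          channels = acceleration_channels(),
                          statistics = default_statistics()) {
  stopifnot(inherits(model, "har_model"))
  cm <- select_channels(session, channels)
  st <- har_stream(window_seconds, channels, cm$sampling_rate)
  end_times <- numeric(0)
  labels <- integer(0)
  for (i in seq_len(nrow(cm$values))) {
    w <- stream_push(st, cm$values[i, ], cm$labels[i])
    if (!is.null(w)) {
      fm <- extract_features(list(w), channels = channels,
                             statistics = statistics)
      end_times <- c(end_times, w$end_time)
      labels <- c(labels, predict(model, fm))
    }
  }
  data.frame(end_time = end_times, label = labels)
}
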