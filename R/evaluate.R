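#' Build a confusion matrix
#'
#' K x K integer counts with rows = actual class and columns = predicted
#' class, over a fixed ordered class list.
#'
#' @param actual,predicted Equal-length integer label vectors; every label
#'   must belong to `classes`.
#' @param classes Ordered class codes; default the sorted union of the
#'   labels observed.
#' @return An object of class `har_confusion` with fields `classes` and
#'   `counts`.
#' @export
confusion_matrix <- function(actual, predicted,
                             classes = sort(unique(c(actual, predicted)))) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  unknown <- setdiff(unique(c(actual, predicted)), classes)
  if (length(unknown))
    stop(sprintf("label(s) not in the class list: %s",
                 paste(unknown, collapse = ", ")))
  fa <- factor(actual, levels = classes)
  fp <- factor(predicted, levels = classes)
  counts <- unclass(table(actual = fa, predicted = fp))
  structure(list(classes = classes, counts = counts),
            class = "har_confusion")
}

#' @export
print.har_confusion <- function(x, ...) {
  cat(sprintf("<har_confusion> %d classes, %d observations\n",
              length(x$classes), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Write a confusion matrix as TSV (and read it back)
#'
#' @param cm A `har_confusion`.
#' @param path TSV path; rows = actual, columns = predicted, both labelled
#'   by class code.
#' @export
write_confusion_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "har_confusion"))
  utils::write.table(cm$counts, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_confusion_tsv
#' @export
read_confusion_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  classes <- suppressWarnings(as.integer(rownames(m)))
  if (anyNA(classes)) classes <- rownames(m)
  dimnames(m) <- list(actual = rownames(m), predicted = colnames(m))
  structure(list(classes = classes, counts = m), class = "har_confusion")
}

#' One-vs-rest metrics for a single class
#'
#' Reduces the multi-class confusion matrix to the 2 x 2 problem of one
#' class against the rest and reports sensitivity `SE = TP/(TP+FN)`,
#' specificity `SP = TN/(TN+FP)`, positive predictive value
#' `PPV = TP/(TP+FP)`, negative predictive value `NPV = TN/(TN+FN)` and the
#' F-score (harmonic mean of SE and PPV). A 0/0 ratio is reported as 0 and
#' the affected metric names are flagged in `degenerate` rather than
#' surfacing as silent `NaN`s.
#'
#' @param cm A [confusion_matrix()].
#' @param class_code A class present in `cm`.
#' @return Named list with `SE`, `SP`, `PPV`, `NPV`, `F` and a character
#'   vector `degenerate`.
#' @export
class_metrics <- function(cm, class_code) {
  stopifnot(inherits(cm, "har_confusion"))
  i <- match(class_code, cm$classes)
  if (is.na(i)) stop(sprintf("class %s not in confusion matrix", class_code))
  m <- cm$counts
  tp <- m[i, i]
  fn <- sum(m[i, ]) - tp
  fp <- sum(m[, i]) - tp
  tn <- sum(m) - tp - fn - fp
  degenerate <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  se <- ratio(tp, tp + fn, "SE")
  sp <- ratio(tn, tn + fp, "SP")
  ppv <- ratio(tp, tp + fp, "PPV")
  npv <- ratio(tn, tn + fn, "NPV")
  f <- if (se + ppv == 0) {
    degenerate <- c(degenerate, "F")
    0
  } else fscore(se, ppv)
  list(SE = se, SP = sp, PPV = ppv, NPV = npv, F = f,
       degenerate = degenerate)
}

#' F-score from sensitivity and precision
#'
#' The harmonic mean `2 * ppv * se / (ppv + se)`, with the convention that
#' it is 0 when both arguments are 0. Symmetric in its arguments and bounded
#' above by both the geometric and the arithmetic mean of the two.
#'
#' @param se,ppv Values in `[0, 1]`.
#' @return The F-score in `[0, 1]`.
#' @export
fscore <- function(se, ppv) {
  if (!is.numeric(se) || !is.numeric(ppv) ||
      any(se < 0 | se > 1) || any(ppv < 0 | ppv > 1))
    stop("se and ppv must lie in [0, 1]")
  ifelse(se + ppv == 0, 0, 2 * ppv * se / (ppv + se))
}

#' Per-class performance report
#'
#' Computes the five one-vs-rest metrics for every class of a confusion
#' matrix plus their macro averages. Printing rounds to two decimals (the
#' usual reporting precision); full precision is retained in the object.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `har_metrics`: a data frame `per_class`
#'   (class, SE, SP, PPV, NPV, F), a named numeric `macro`, and the list of
#'   degenerate flags per class.
#' @export
metrics_report <- function(cm) {
  stopifnot(inherits(cm, "har_confusion"))
  rows <- lapply(cm$classes, function(cl) class_metrics(cm, cl))
  per_class <- data.frame(
    class = cm$classes,
    SE = vapply(rows, `[[`, numeric(1), "SE"),
    SP = vapply(rows, `[[`, numeric(1), "SP"),
    PPV = vapply(rows, `[[`, numeric(1), "PPV"),
    NPV = vapply(rows, `[[`, numeric(1), "NPV"),
    F = vapply(rows, `[[`, numeric(1), "F"))
  macro <- colMeans(per_class[, c("SE", "SP", "PPV", "NPV", "F")])
  structure(list(per_class = per_class, macro = macro,
                 degenerate = lapply(rows, `[[`, "degenerate")),
            class = "har_metrics")
}

#' @export
print.har_metrics <- function(x, ...) {
  df <- x$per_class
  out <- data.frame(Activity = paste0("L", df$class),
                    lapply(df[, -1], function(v) sprintf("%.2f", v)),
                    check.names = FALSE)
  names(out) <- c("Activity", "SE", "SP", "PPV", "NPV", "F-score")
  print(out, row.names = FALSE)
  cat(sprintf("macro: SE %.2f SP %.2f PPV %.2f NPV %.2f F %.2f\n",
              x$macro["SE"], x$macro["SP"], x$macro["PPV"],
              x$macro["NPV"], x$macro["F"]))
  invisible(x)
}

#' Write a per-class metrics report as TSV
#'
#' Columns Activity, SE, SP, PPV, NPV, F-score, one row per class, values at
#' two decimals — the shape of a standard per-activity performance table.
#'
#' @param report A `har_metrics` object.
#' @param path TSV path.
#' @export
write_metrics_tsv <- function(report, path) {
  stopifnot(inherits(report, "har_metrics"))
  df <- report$per_class
  out <- data.frame(Activity = paste0("L", df$class),
                    SE = sprintf("%.2f", df$SE),
                    SP = sprintf("%.2f", df$SP),
                    PPV = sprintf("%.2f", df$PPV),
                    NPV = sprintf("%.2f", df$NPV),
                    `F-score` = sprintf("%.2f", df$F),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assign observations to cross-validation folds
#'
#' Seeded fold assignment for k-fold cross-validation. With
#' `stratified = TRUE` (default) each class is spread as evenly as possible
#' across the k folds; every class then needs at least k members. The
#' assignment is a partition: each observation lands in exactly one fold.
#'
#' @param labels Integer label vector (one per observation).
#' @param k Number of folds (>= 2).
#' @param stratified Stratify folds by label?
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1:k`, one per observation.
#' @export
kfold_assign <- function(labels, k = 10L, stratified = TRUE, seed = 1L) {
  n <- length(labels)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("fewer observations than folds")
  set.seed(seed)
  folds <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop(sprintf(paste0("class %s has %d members, fewer than k = %d ",
                            "folds; use stratified = FALSE"),
                     cl, length(idx), k))
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), n))
  }
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' The offline evaluation protocol: for each repetition a fresh seeded
#' shuffle partitions the windows into k near-equal folds (stratified by
#' label by default); each fold serves once as test set, so every window is
#' tested exactly once per repetition. Fold confusion matrices are summed
#' over folds and repetitions — the aggregate total equals
#' `repetitions x windows` — and the per-class metrics are computed once on
#' the aggregate. Repetition `r` uses seed `seed + r`, making the whole run
#' reproducible from one base seed.
#'
#' @param features A `feature_matrix`.
#' @param method,control Passed to [har_train()].
#' @param k Folds (default 10).
#' @param repetitions Repetitions of the whole k-fold process (default 100).
#' @param stratified Stratify folds by label (default `TRUE`).
#' @param seed Base seed.
#' @return An object of class `har_cv`: aggregated `confusion`
#'   (`har_confusion`), `metrics` (`har_metrics`), and the run settings.
#' @export
har_cv <- function(features, method = "decision_tree", control = list(),
                   k = 10L, repetitions = 100L, stratified = TRUE,
                   seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  if (repetitions < 1L) stop("repetitions must be >= 1")
  classes <- sort(unique(features$labels))
  total <- matrix(0L, length(classes), length(classes),
                  dimnames = list(actual = classes, predicted = classes))
  n <- nrow(features$values)
  for (r in seq_len(repetitions)) {
    folds <- kfold_assign(features$labels, k = k, stratified = stratified,
                          seed = seed + r)
    for (f in seq_len(k)) {
      test <- folds == f
      train_fm <- subset_features(features, !test)
      test_fm <- subset_features(features, test)
      model <- har_train(train_fm, method = method, control = control,
                         seed = seed)
      pred <- predict(model, test_fm)
      cm <- confusion_matrix(test_fm$labels, pred, classes = classes)
      total <- total + cm$counts
    }
  }
  confusion <- structure(list(classes = classes, counts = total),
                         class = "har_confusion")
  structure(list(confusion = confusion, metrics = metrics_report(confusion),
                 k = k, repetitions = repetitions, stratified = stratified,
                 method = method, seed = seed, n_windows = n),
            class = "har_cv")
}

subset_features <- function(features, keep) {
  structure(list(values = features$values[keep, , drop = FALSE],
                 feature_names = features$feature_names,
                 labels = features$labels[keep],
                 end_times = features$end_times[keep]),
            class = "feature_matrix")
}

#' @export
print.har_cv <- function(x, ...) {
  cat(sprintf(
    "<har_cv> %s, %d-fold x %d repetition(s)%s on %d windows\n",
    x$method, x$k, x$repetitions,
    if (x$stratified) " (stratified)" else "", x$n_windows))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.har_cv <- function(object, ...) {
  print(object)
  off <- sum(object$confusion$counts) - sum(diag(object$confusion$counts))
  cat(sprintf("aggregated total %d, off-diagonal %d (%.2f%%)\n",
              sum(object$confusion$counts), off,
              100 * off / sum(object$confusion$counts)))
  invisible(object)
}

#' Delay-aligned online evaluation
#'
#' The runtime evaluation protocol: each streaming prediction, stamped with
#' the end time of the window it came from, is compared against the ground
#' truth over that window's time span `[end_time - window_seconds,
#' end_time)`. Windows whose truth labels are not unanimous (transitions
#' between activities) or that touch the null class (label 0) are excluded,
#' since no null-class rejection is implemented; the remaining pairs are
#' tallied into a confusion matrix. The half-window [segmentation_delay()]
#' is exactly the offset that centres such a window-end prediction on the
#' activity being performed.
#'
#' @param end_times Prediction timestamps in seconds (window ends); all
#'   windows must lie within the truth timeline.
#' @param predicted Integer predicted label per prediction.
#' @param truth Per-sample ground-truth labels at `sampling_rate`.
#' @param sampling_rate Hz of the truth stream.
#' @param window_seconds Window duration used by the recognizer.
#' @param classes Class codes for the confusion matrix; default sorted
#'   union of the labels scored.
#' @return A `har_confusion` over the non-transition windows, with
#'   attribute `n_excluded`.
#' @export
online_evaluate <- function(end_times, predicted, truth, sampling_rate,
                            window_seconds = 2, classes = NULL) {
  if (length(end_times) != length(predicted))
    stop("end_times and predicted must have equal length")
  n <- length(truth)
  actual <- integer(0)
  pred <- integer(0)
  excluded <- 0L
  for (i in seq_along(end_times)) {
    end_i <- as.integer(round(end_times[i] * sampling_rate))
    start_i <- as.integer(round(
      (end_times[i] - window_seconds) * sampling_rate))
    if (start_i < 0L || end_i > n)
      stop(sprintf("prediction at t=%g s lies outside the truth timeline",
                   end_times[i]))
    span <- truth[(start_i + 1L):end_i]
    if (length(unique(span)) != 1L || span[1L] == 0L) {
      excluded <- excluded + 1L
      next
    }
    actual <- c(actual, span[1L])
    pred <- c(pred, predicted[i])
  }
  cm <- if (is.null(classes)) confusion_matrix(actual, pred)
        else confusion_matrix(actual, pred, classes = classes)
  attr(cm, "n_excluded") <- excluded
  cm
}
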