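#' Fit an activity classifier
#'
#' The central fitting function. Three classifier families are supported:
#'
#' * `"decision_tree"` — a C4.5-style classification tree (impurity-based
#'   splits using information gain, optional cost-complexity pruning),
#'   delegated to [rpart::rpart()]. This is the recognition model's default.
#' * `"gaussian_nb"` — Gaussian naive Bayes via [e1071::naiveBayes()].
#' * `"zeror"` — the majority-class baseline; ties break toward the
#'   smallest label code.
#'
#' Fitting is deterministic given the feature matrix, the control settings
#' and the seed (recorded for provenance; the supported learners are
#' themselves deterministic). A training set with a single class yields a
#' degenerate single-leaf model, not an error.
#'
#' @param features A `feature_matrix` from [extract_features()] (or
#'   [read_features_csv()]).
#' @param method Classifier kind.
#' @param control Named list of hyperparameters for the tree: `min_leaf`
#'   (minimum observations per leaf, default 2), `prune` (logical, default
#'   `TRUE`; `FALSE` grows the full tree, complexity penalty 0), `cp`
#'   (cost-complexity parameter when pruning, default 0.01).
#' @param seed Integer seed recorded in the model.
#' @return An object of class `har_model`.
#' @export
har_train <- function(features,
                      method = c("decision_tree", "gaussian_nb", "zeror"),
                      control = list(), seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(features, "feature_matrix"))
  if (nrow(features$values) == 0L) stop("empty feature matrix")
  if (anyNA(features$values)) stop("feature matrix contains missing values")
  classes <- sort(unique(features$labels))
  if (method == "gaussian_nb" && length(classes) < 2L)
    stop("gaussian_nb needs at least 2 distinct labels")
  y <- factor(features$labels, levels = classes)
  df <- as.data.frame(features$values, check.names = FALSE)

  ctl <- utils::modifyList(list(min_leaf = 2L, prune = TRUE, cp = 0.01),
                           control)
  set.seed(seed)
  fit <- switch(method,
    zeror = {
      tab <- table(y)                       # levels sorted ascending
      list(modal = classes[which.max(tab)]) # first max = smallest code
    },
    gaussian_nb = e1071::naiveBayes(x = df, y = y),
    decision_tree = {
      if (length(classes) == 1L)            # degenerate single-leaf model
        return(structure(list(method = method, control = ctl, seed = seed,
                              fit = list(constant = classes),
                              classes = classes,
                              feature_names = features$feature_names),
                         class = "har_model"))
      dat <- df
      dat$.label <- y
      rpart::rpart(.label ~ ., data = dat, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(
                     minbucket = ctl$min_leaf,
                     minsplit = max(2L, 2L * ctl$min_leaf),
                     cp = if (ctl$prune) ctl$cp else 0,
                     xval = 0))
    })
  structure(list(method = method, control = ctl, seed = seed, fit = fit,
                 classes = classes, feature_names = features$feature_names),
            class = "har_model")
}

#' Predict activity labels
#'
#' @param object A [har_train()] model.
#' @param newdata A `feature_matrix`, or a numeric matrix / data frame whose
#'   columns match the training feature names.
#' @param ... Unused.
#' @return Integer label vector, one per row, drawn from the training
#'   classes.
#' @export
predict.har_model <- function(object, newdata, ...) {
  df <- as_feature_df(newdata)
  missing <- setdiff(object$feature_names, names(df))
  if (length(missing))
    stop(sprintf("newdata lacks feature column(s): %s",
                 paste(missing, collapse = ", ")))
  df <- df[, object$feature_names, drop = FALSE]
  switch(object$method,
    zeror = rep(object$fit$modal, nrow(df)),
    gaussian_nb = as.integer(as.character(
      predict(object$fit, newdata = df, type = "class"))),
    decision_tree = {
      if (inherits(object$fit, "rpart")) {
        as.integer(as.character(
          predict(object$fit, newdata = df, type = "class")))
      } else if (!is.null(object$fit$constant)) {
        rep(object$fit$constant, nrow(df))
      } else stop("unrecognized fitted tree object")
    })
}

as_feature_df <- function(x) {
  if (inherits(x, "feature_matrix"))
    return(as.data.frame(x$values, check.names = FALSE))
  if (is.matrix(x)) return(as.data.frame(x, check.names = FALSE))
  if (is.data.frame(x)) return(x)
  stop("newdata must be a feature_matrix, matrix or data frame")
}

#' @export
print.har_model <- function(x, ...) {
  cat(sprintf("<har_model> %s over %d features, classes {%s}\n",
              x$method, length(x$feature_names),
              paste(x$classes, collapse = ",")))
  invisible(x)
}

#' @export
summary.har_model <- function(object, ...) {
  print(object)
  if (object$method == "zeror")
    cat("  modal label:", object$fit$modal, "\n")
  if (object$method == "decision_tree" && inherits(object$fit, "rpart")) {
    leaves <- sum(object$fit$frame$var == "<leaf>")
    cat(sprintf("  tree with %d leaves (min_leaf=%d, %s)\n", leaves,
                object$control$min_leaf,
                if (object$control$prune)
                  sprintf("pruned, cp=%g", object$control$cp)
                else "unpruned"))
  }
  invisible(object)
}

MODEL_FORMAT <- "harwear_model"
MODEL_VERSION <- 1L

#' Persist and restore trained models
#'
#' Models are written as a self-describing versioned archive (an RDS file
#' wrapping the model with a format tag and version number); loading checks
#' both and the roundtrip is lossless, so predictions after a save/load
#' cycle are bitwise identical.
#'
#' @param model A `har_model`.
#' @param path File path.
#' @return `save_har_model()`: `path` invisibly; `load_har_model()`: the
#'   restored `har_model`.
#' @export
save_har_model <- function(model, path) {
  stopifnot(inherits(model, "har_model"))
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_VERSION,
               model = model), path)
  invisible(path)
}

#' @rdname save_har_model
#' @export
load_har_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e)
                    stop(sprintf("cannot load model file %s: %s", path,
                                 conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT))
    stop(sprintf("%s is not a harwear model file", path))
  if (!identical(obj$version, MODEL_VERSION))
    stop(sprintf("model file version %s not supported (expected %d)",
                 obj$version, MODEL_VERSION))
  obj$model
}
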