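# Small in-code fixtures shared across the suite.

# a 2-channel layout for compact log/json tests (2 signal cols + label)
tiny_layout <- function() {
  list(device_spec("chest", list(sensor_spec("acc", "m/s^2", c("x", "y")))))
}

tiny_session <- function(values, labels, fs = 50) {
  n <- nrow(values)
  md <- har_metadata("sess1", "subj1", 0, if (n > 0) (n - 1) / fs else 0,
                     fs, tiny_layout())
  har_session(md, values, labels)
}

# random channel_matrix with reproducible content
random_matrix <- function(n = 100, channels = 3, fs = 50, seed = 1,
                          labels = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(n * channels), n, channels,
              dimnames = list(NULL, paste0("c", seq_len(channels))))
  if (is.null(labels)) labels <- sample(1:3, n, replace = TRUE)
  channel_matrix(v, labels, fs)
}

# linearly separable toy features: 1 feature, class 1 below 0, class 2 above
separable_features <- function(n_per_class = 5) {
  v <- matrix(c(seq(-1, -0.2, length.out = n_per_class),
                seq(0.2, 1, length.out = n_per_class)), ncol = 1,
              dimnames = list(NULL, "f:mean"))
  structure(list(values = v, feature_names = "f:mean",
                 labels = rep(c(1L, 2L), each = n_per_class),
                 end_times = seq_len(2 * n_per_class) * 2),
            class = "feature_matrix")
}

# feature matrix straight from labels/values for evaluation tests
features_from <- function(values, labels) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  structure(list(values = values, feature_names = colnames(values),
                 labels = as.integer(labels),
                 end_times = seq_len(nrow(values)) * 2),
            class = "feature_matrix")
}
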