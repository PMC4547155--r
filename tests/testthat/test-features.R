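test_that("window statistics match hand arithmetic", {
  x <- c(1, 2, 3, 4)
  expect_equal(window_statistic(x, "mean"), 2.5)
  expect_equal(window_statistic(x, "variance"), 5 / 3)
  expect_equal(window_statistic(x, "std"), sqrt(5 / 3))
  expect_equal(window_statistic(x, "max"), 4)
  expect_equal(window_statistic(x, "min"), 1)
  expect_equal(window_statistic(x, "zcr"), 0)
  # centred signs are -,-,+,+ : one crossing
  expect_equal(window_statistic(x, "mcr"), 1)
})

test_that("zero-crossing rule: zeros inherit the last nonzero sign", {
  expect_equal(window_statistic(c(1, -1, 1, -1), "zcr"), 3)
  expect_equal(window_statistic(c(1, 0, -1), "zcr"), 1)
  expect_equal(window_statistic(c(0, 0, 1), "zcr"), 0)   # leading zeros +
  expect_equal(window_statistic(c(0, 0, -1), "zcr"), 1)
  expect_equal(window_statistic(c(-1, 0, 0, 1), "zcr"), 1)
  # invariant under positive scaling
  set.seed(11)
  x <- rnorm(200)
  expect_equal(window_statistic(3.7 * x, "zcr"),
               window_statistic(x, "zcr"))
})

test_that("statistic preconditions are enforced", {
  expect_error(window_statistic(numeric(0), "mean"), "non-empty")
  expect_error(window_statistic(1, "variance"), "at least 2")
  expect_error(window_statistic(1, "std"), "at least 2")
  expect_error(window_statistic(c(1, 2), "median"))
})

test_that("feature matrix has channels-outer, statistics-inner layout", {
  p <- subject_profile("s1")
  s <- generate_session(p, har_schedule(1:3, 4), 50, seed = 2)
  fm <- har_features(s)
  expect_equal(ncol(fm$values), 36)  # 9 channels x 4 statistics
  expect_equal(fm$feature_names[1:4],
               paste0("chest/acc/x:", c("mean", "std", "max", "min")))
  expect_equal(nrow(fm$values), length(fm$labels))
  expect_error(extract_features(make_windows(select_channels(s), 2),
                                statistics = "kurtosis"), "unknown")
})

test_that("constant windows give degenerate statistics", {
  v <- matrix(2.5, 100, 1, dimnames = list(NULL, "c1"))
  w <- make_windows(channel_matrix(v, rep(1L, 100), 50), 2)
  fm <- extract_features(w, statistics = c("mean", "std", "max", "min",
                                           "zcr", "mcr"))
  row <- fm$values[1, ]
  expect_equal(unname(row[c("c1:mean", "c1:max", "c1:min")]),
               c(2.5, 2.5, 2.5))
  expect_equal(unname(row["c1:std"]), 0)
  expect_equal(unname(row["c1:zcr"]), 0)
  expect_equal(unname(row["c1:mcr"]), 0)
})

test_that("every feature cell equals a brute-force recomputation", {
  m <- random_matrix(n = 500, channels = 3, fs = 50, seed = 13)
  windows <- make_windows(m, 2)
  stats <- c("mean", "variance", "std", "max", "min", "zcr", "mcr")
  fm <- extract_features(windows, statistics = stats)
  brute <- function(x, s) {  # independent oracle, base R only
    switch(s,
           mean = sum(x) / length(x),
           variance = sum((x - sum(x) / length(x))^2) / (length(x) - 1),
           std = sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1)),
           max = sort(x, decreasing = TRUE)[1],
           min = sort(x)[1],
           zcr = {
             # per-sample sign with zero-inheritance, then count diffs
             sgn <- numeric(length(x))
             cur <- 1  # leading zeros count as positive
             for (i in seq_along(x)) {
               s <- sign(x[i])
               if (s != 0) cur <- s
               sgn[i] <- cur
             }
             sum(sgn[-1] != sgn[-length(sgn)])
           },
           mcr = brute(x - sum(x) / length(x), "zcr"))
  }
  for (wi in seq_along(windows)) {
    for (ch in colnames(m$values)) {
      slice <- windows[[wi]]$values[, ch]
      for (s in stats) {
        expect_equal(unname(fm$values[wi, paste0(ch, ":", s)]),
                     brute(slice, s),
                     info = sprintf("window %d %s %s", wi, ch, s))
      }
    }
  }
  # min <= mean <= max per channel-window triple
  for (ch in colnames(m$values)) {
    expect_true(all(fm$values[, paste0(ch, ":min")] <=
                      fm$values[, paste0(ch, ":mean")]))
    expect_true(all(fm$values[, paste0(ch, ":mean")] <=
                      fm$values[, paste0(ch, ":max")]))
    expect_true(all(fm$values[, paste0(ch, ":std")] >= 0))
  }
})

test_that("feature CSV roundtrips", {
  m <- random_matrix(n = 300, channels = 2, fs = 50, seed = 8)
  fm <- extract_features(make_windows(m, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fm, path)
  back <- read_features_csv(path)
  expect_identical(back$feature_names, fm$feature_names)
  expect_identical(back$labels, fm$labels)
  expect_equal(unname(back$values), unname(fm$values))
})
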