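test_that("confusion counts match direct tallies", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), classes = c(1, 2))
  expect_equal(unname(cm$counts), matrix(c(1, 0, 1, 1), 2))
  perfect <- confusion_matrix(1:4, 1:4, classes = 1:4)
  expect_equal(unname(perfect$counts), diag(4))
  expect_error(confusion_matrix(1:3, 1:2), "equal length")
  expect_error(confusion_matrix(c(1, 9), c(1, 1), classes = 1:2), "9")
})

test_that("confusion counts equal a brute-force count on a random fixture", {
  set.seed(17)
  actual <- sample(1:5, 500, replace = TRUE)
  predicted <- sample(1:5, 500, replace = TRUE)
  cm <- confusion_matrix(actual, predicted, classes = 1:5)
  for (i in 1:5) for (j in 1:5)
    expect_equal(cm$counts[i, j], sum(actual == i & predicted == j))
  expect_equal(sum(cm$counts), 500)
})

test_that("one-vs-rest metrics match hand arithmetic", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), classes = c(1, 2))
  m <- class_metrics(cm, 1)
  expect_equal(m$SE, 0.5)
  expect_equal(m$SP, 1)
  expect_equal(m$PPV, 1)
  expect_equal(m$NPV, 0.5)
  expect_equal(m$F, 2 / 3)
  expect_error(class_metrics(cm, 7), "not in")
})

test_that("a diagonal confusion matrix scores 1.00 everywhere", {
  cm <- confusion_matrix(rep(1:12, each = 10), rep(1:12, each = 10),
                         classes = 1:12)
  rep_ <- metrics_report(cm)
  for (col in c("SE", "SP", "PPV", "NPV", "F"))
    expect_equal(rep_$per_class[[col]], rep(1, 12))
  expect_equal(unname(rep_$macro["F"]), 1)
})

test_that("an all-wrong two-class matrix scores 0 with degeneracy flags", {
  cm <- confusion_matrix(c(rep(1, 5), rep(2, 5)),
                         c(rep(2, 5), rep(1, 5)), classes = 1:2)
  for (cl in 1:2) {
    m <- class_metrics(cm, cl)
    expect_equal(m$SE, 0)
    expect_equal(m$SP, 0)
    expect_true("F" %in% m$degenerate)
  }
})

test_that("fscore is the harmonic mean with the 0/0 convention", {
  expect_equal(fscore(1, 1), 1)
  expect_equal(fscore(0, 0), 0)
  expect_equal(round(fscore(0.95, 0.97), 2), 0.96)
  expect_equal(round(fscore(1.00, 0.88), 2), 0.94)
  expect_error(fscore(1.2, 0.5), "\\[0, 1\\]")
  # symmetry and mean bounds
  set.seed(3)
  se <- runif(50); ppv <- runif(50)
  expect_equal(fscore(se, ppv), fscore(ppv, se))
  expect_true(all(fscore(se, ppv) <= sqrt(se * ppv) + 1e-12))
  expect_true(all(fscore(se, ppv) <= (se + ppv) / 2 + 1e-12))
})

test_that("metrics are invariant under simultaneous class permutation", {
  set.seed(23)
  actual <- sample(1:4, 300, replace = TRUE)
  predicted <- sample(1:4, 300, replace = TRUE)
  cm <- confusion_matrix(actual, predicted, classes = 1:4)
  perm <- c(3, 1, 4, 2)
  cmp <- confusion_matrix(perm[actual], perm[predicted], classes = 1:4)
  for (cl in 1:4) {
    a <- class_metrics(cm, cl)
    b <- class_metrics(cmp, perm[cl])
    for (k in c("SE", "SP", "PPV", "NPV", "F"))
      expect_equal(a[[k]], b[[k]])
    # SE * (TP + FN) recovers TP exactly
    expect_equal(a$SE * sum(cm$counts[cl, ]), cm$counts[cl, cl])
  }
})

test_that("fold assignment is a stratified partition", {
  set.seed(31)
  labels <- sample(1:3, 60, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  for (r in 1:5) {
    folds <- kfold_assign(labels, k = 5, seed = 100 + r)
    expect_length(folds, 60)                    # every obs in exactly 1 fold
    expect_setequal(unique(folds), 1:5)
    for (cl in 1:3) {                           # near-equal class spread
      per <- table(factor(folds[labels == cl], levels = 1:5))
      expect_lte(max(per) - min(per), 1)
    }
  }
  expect_error(kfold_assign(c(1, rep(2, 20)), k = 5), "stratified = FALSE")
  un <- kfold_assign(c(1, rep(2, 20)), k = 5, stratified = FALSE)
  expect_length(un, 21)
})

test_that("repeated CV tests every window once per repetition", {
  m <- random_matrix(n = 4000, channels = 2, fs = 50, seed = 41,
                     labels = rep(1:2, 2000))
  fm <- extract_features(make_windows(m, 2))  # 40 windows
  cv <- har_cv(fm, method = "zeror", k = 10, repetitions = 2, seed = 1)
  expect_equal(sum(cv$confusion$counts), 2 * 40)
  # the emitted fold indices per repetition partition the windows
  for (r in 1:2) {
    folds <- kfold_assign(fm$labels, k = 10, seed = 1 + r)
    expect_equal(as.vector(table(folds)), rep(4, 10))
  }
})

test_that("zeror under CV gives SE 1 for the majority class, 0 elsewhere", {
  labs <- c(rep(1L, 20), rep(2L, 6), rep(3L, 6))
  fm <- features_from(matrix(rnorm(32), 32, 1), labs)
  cv <- har_cv(fm, method = "zeror", k = 3, repetitions = 2, seed = 9)
  rep_ <- cv$metrics$per_class
  expect_equal(rep_$SE[rep_$class == 1], 1)
  expect_equal(rep_$SE[rep_$class == 2], 0)
  expect_equal(rep_$SE[rep_$class == 3], 0)
})

test_that("reports and confusion matrices roundtrip through TSV", {
  set.seed(5)
  cm <- confusion_matrix(sample(1:3, 90, TRUE), sample(1:3, 90, TRUE),
                         classes = 1:3)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_confusion_tsv(cm, cpath)
  back <- read_confusion_tsv(cpath)
  expect_equal(unname(back$counts), unname(cm$counts))
  rpath <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_tsv(metrics_report(cm), rpath)
  tab <- utils::read.delim(rpath, check.names = FALSE)
  expect_equal(names(tab), c("Activity", "SE", "SP", "PPV", "NPV",
                             "F-score"))
  expect_equal(nrow(tab), 3)
})
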