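test_that("log reading synthesizes timestamps and parses labels", {
  path <- withr::local_tempfile(fileext = ".log")
  writeLines(c("1.0 2.0 1", "3.5 4.5 1", "5.0 6.0 2"), path)
  s <- read_mhealth_log(path, column_map = tiny_layout(),
                        sampling_rate = 50, subject_id = "s1")
  expect_equal(nrow(s$values), 3)
  expect_equal(s$timestamps, c(0, 0.02, 0.04))
  expect_identical(s$labels, c(1L, 1L, 2L))
  expect_equal(unname(s$values[2, ]), c(3.5, 4.5))
})

test_that("write/read log roundtrip is lossless, including label 0", {
  set.seed(7)
  v <- matrix(rnorm(40), 20, 2)
  labs <- c(rep(0L, 5), rep(3L, 15))
  s <- tiny_session(v, labs)
  path <- withr::local_tempfile(fileext = ".log")
  write_mhealth_log(s, path)
  lines <- readLines(path)
  expect_length(lines[nzchar(lines)], 20)
  expect_true(all(vapply(strsplit(lines[1:5], " "),
                         function(x) x[3] == "0", logical(1))))
  s2 <- read_mhealth_log(path, column_map = tiny_layout(),
                         sampling_rate = 50, subject_id = "subj1")
  expect_identical(unname(s2$values), unname(s$values))
  expect_identical(s2$labels, s$labels)
})

test_that("malformed logs raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".log")
  writeLines(c("1.0 2.0"), path)  # 2 cols under a 3-col layout
  expect_error(read_mhealth_log(path, tiny_layout()), "line 1")
  writeLines(c("1.0 2.0 1", "1.0 oops 1"), path)
  expect_error(read_mhealth_log(path, tiny_layout()), "line 2")
  writeLines(character(0), path)
  expect_error(read_mhealth_log(path, tiny_layout()), "empty")
})

test_that("json document holds metadata once and roundtrips", {
  s <- tiny_session(matrix(c(1.5, 2.25, -3.125, 0.1, 9.81, 1e-7),
                           3, 2, byrow = TRUE), c(1L, 1L, 2L))
  json <- session_to_json(s)
  expect_equal(length(gregexpr("\"sampling_rate\"", json)[[1]]), 1)
  doc <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  expect_equal(nrow(doc$samples$values), 3)
  s2 <- session_from_json(json)
  expect_identical(unname(s2$values), unname(s$values))
  expect_identical(s2$labels, s$labels)
  # idempotence: a re-serialized parse is byte-stable
  expect_identical(session_to_json(s2), json)
})

test_that("empty-sample session serializes with an empty sample array", {
  s <- tiny_session(matrix(numeric(0), 0, 2), integer(0))
  s2 <- session_from_json(session_to_json(s))
  expect_equal(nrow(s2$values), 0)
  expect_identical(s2$metadata$session_id, "sess1")
})

test_that("json size grows linearly with a constant metadata overhead", {
  # 1 Hz so every timestamp and end time serializes at the same width
  mk <- function(n) tiny_session(matrix(1.5, n, 2), rep(1L, n), fs = 1)
  sizes <- vapply(1:3, function(n) nchar(session_to_json(mk(n))),
                  numeric(1))
  expect_equal(sizes[3] - sizes[2], sizes[2] - sizes[1])
})

test_that("select_channels copies values verbatim in requested order", {
  p <- subject_profile("s1")
  s <- generate_session(p, har_schedule(1:2, 2), 50, seed = 5)
  cm <- select_channels(s, acceleration_channels())
  expect_equal(ncol(cm$values), 9)
  expect_identical(cm$channel_names, acceleration_channels())
  for (ch in acceleration_channels())
    expect_identical(cm$values[, ch], unname(s$values[, ch]))
  one <- select_channels(s, "left-ankle/acc/z")
  expect_identical(one$values[, 1], unname(s$values[, "left-ankle/acc/z"]))
  expect_identical(cm$labels, s$labels)
  expect_error(select_channels(s, "chest/acc/w"), "chest/acc/w")
})

test_that("session invariants are enforced", {
  expect_error(har_metadata("a", "b", 10, 5, 50, tiny_layout()),
               "end_time")
  expect_error(har_metadata("a", "b", 0, 5, -1, tiny_layout()),
               "sampling_rate")
  md <- har_metadata("a", "b", 0, 1, 50, tiny_layout())
  expect_error(har_session(md, matrix(0, 2, 2), c(1L, 13L)), "0..12")
  expect_error(har_session(md, matrix(0, 2, 2), c(1L, 1L),
                           timestamps = c(0, 0.5)), "1/sampling_rate")
  expect_error(har_session(md, matrix(0, 200, 2), rep(1L, 200)),
               "more samples")
})
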