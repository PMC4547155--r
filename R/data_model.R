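#' Sensor and device descriptors
#'
#' A `sensor_spec` describes one sensing modality on a device (its type,
#' measurement units and axis names); a `device_spec` groups the sensors worn
#' at one body location. Channel names are formed as
#' `"<device>/<sensor>/<axis>"` and must be globally unique within a session.
#'
#' @param sensor_type Short sensor type code, e.g. `"acc"`, `"gyro"`,
#'   `"mag"`, `"ecg"`.
#' @param units Measurement units, e.g. `"m/s^2"`.
#' @param axes Character vector of axis names (non-empty), e.g.
#'   `c("x", "y", "z")` or `c("lead1", "lead2")`.
#' @return An object of class `sensor_spec` / `device_spec`.
#' @export
sensor_spec <- function(sensor_type, units, axes) {
  stopifnot(is.character(sensor_type), length(sensor_type) == 1L,
            is.character(units), length(units) == 1L)
  if (length(axes) < 1L) stop("a sensor needs at least one axis")
  structure(list(sensor_type = sensor_type, units = units,
                 axes = as.character(axes)),
            class = "sensor_spec")
}

#' @param device_name Body location of the device, e.g. `"chest"`.
#' @param sensors List of `sensor_spec` objects (at least one).
#' @rdname sensor_spec
#' @export
device_spec <- function(device_name, sensors) {
  stopifnot(is.character(device_name), length(device_name) == 1L)
  if (length(sensors) < 1L) stop("a device needs at least one sensor")
  structure(list(device_name = device_name, sensors = sensors),
            class = "device_spec")
}

#' Session metadata
#'
#' Session-level metadata is stored once per session, never per sample: the
#' identifiers, the recording interval, the sampling rate and the device /
#' sensor / axis tree that fixes the channel layout.
#'
#' @param session_id,subject_id Identifier strings.
#' @param start_time,end_time Seconds; `end_time >= start_time`.
#' @param sampling_rate Sampling rate in Hz (positive).
#' @param devices Ordered list of [device_spec()] objects with unique names.
#' @return An object of class `har_metadata`.
#' @export
har_metadata <- function(session_id, subject_id, start_time, end_time,
                         sampling_rate, devices) {
  if (end_time < start_time) stop("end_time must be >= start_time")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  dn <- vapply(devices, function(d) d$device_name, character(1))
  if (anyDuplicated(dn)) stop("device names must be unique")
  md <- structure(list(session_id = as.character(session_id),
                       subject_id = as.character(subject_id),
                       start_time = as.numeric(start_time),
                       end_time = as.numeric(end_time),
                       sampling_rate = as.numeric(sampling_rate),
                       devices = devices),
                  class = "har_metadata")
  nm <- channel_names(md)
  if (anyDuplicated(nm)) stop("channel names must be globally unique")
  md
}

#' Channel names declared by a metadata object or channel layout
#'
#' @param x A `har_metadata` object or a list of `device_spec`s.
#' @return Character vector `"<device>/<sensor>/<axis>"` in declaration order.
#' @export
channel_names <- function(x) {
  devices <- if (inherits(x, "har_metadata")) x$devices else x
  unlist(lapply(devices, function(d) {
    unlist(lapply(d$sensors, function(s) {
      paste(d$device_name, s$sensor_type, s$axes, sep = "/")
    }))
  }), use.names = FALSE)
}

#' Construct a recording session
#'
#' A session is the central container: metadata plus an ordered, regularly
#' sampled multi-channel stream with a per-sample integer activity label
#' (0 = null/transition, 1..12 = the activity set).
#'
#' @param metadata A [har_metadata()] object.
#' @param values Numeric matrix, samples x channels, columns in declared
#'   channel order.
#' @param labels Integer vector of per-sample activity codes in `0:12`.
#' @param timestamps Seconds from session start; defaults to
#'   `(0:(n-1)) / sampling_rate`. Must be strictly increasing with gaps of
#'   `1/sampling_rate` (tolerance 1e-9 s).
#' @return An object of class `har_session`.
#' @export
har_session <- function(metadata, values, labels, timestamps = NULL) {
  stopifnot(inherits(metadata, "har_metadata"))
  values <- as.matrix(values)
  nm <- channel_names(metadata)
  if (ncol(values) != length(nm))
    stop(sprintf("values has %d columns but metadata declares %d channels",
                 ncol(values), length(nm)))
  colnames(values) <- nm
  n <- nrow(values)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels must match sample count")
  if (n > 0 && (min(labels) < 0L || max(labels) > 12L))
    stop("labels must lie in 0..12")
  fs <- metadata$sampling_rate
  if (is.null(timestamps)) {
    timestamps <- if (n > 0) (seq_len(n) - 1) / fs else numeric(0)
  }
  if (length(timestamps) != n) stop("timestamps must match sample count")
  if (n > 1) {
    gaps <- diff(timestamps)
    if (any(gaps <= 0)) stop("timestamps must be strictly increasing")
    if (any(abs(gaps - 1 / fs) > 1e-9))
      stop("timestamp gaps must equal 1/sampling_rate within 1e-9 s")
  }
  if (n > (metadata$end_time - metadata$start_time) * fs + 1 + 1e-9)
    stop("more samples than the recording interval admits")
  structure(list(metadata = metadata, timestamps = timestamps,
                 values = values, labels = labels),
            class = "har_session")
}

#' @export
print.har_session <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<har_session> %s (subject %s)\n", md$session_id, md$subject_id))
  cat(sprintf("  %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), md$sampling_rate,
              if (nrow(x$values)) nrow(x$values) / md$sampling_rate else 0))
  labs <- sort(unique(x$labels))
  cat("  labels present:", paste(labs, collapse = " "), "\n")
  invisible(x)
}

#' Default multi-device channel layout
#'
#' The layout of the public three-device recordings this package mirrors:
#' chest accelerometer (x,y,z), chest 2-lead ECG, left-ankle accelerometer /
#' gyroscope / magnetometer, right-wrist accelerometer / gyroscope /
#' magnetometer — 23 signal columns, followed by one integer label column in
#' log files. The order is configurable because it is a property of the file
#' dialect, not of the method.
#'
#' @return A list of [device_spec()]s declaring 23 channels.
#' @export
mhealth_column_map <- function() {
  acc <- function() sensor_spec("acc", "m/s^2", c("x", "y", "z"))
  gyro <- function() sensor_spec("gyro", "deg/s", c("x", "y", "z"))
  mag <- function() sensor_spec("mag", "uT", c("x", "y", "z"))
  list(
    device_spec("chest", list(acc(), sensor_spec("ecg", "mV",
                                                 c("lead1", "lead2")))),
    device_spec("left-ankle", list(acc(), gyro(), mag())),
    device_spec("right-wrist", list(acc(), gyro(), mag()))
  )
}

#' The nine acceleration channels used for activity recognition
#'
#' Triaxial acceleration from the chest, left-ankle and right-wrist devices;
#' the modality the recognition model is built on.
#'
#' @return Character vector of 9 channel names.
#' @export
acceleration_channels <- function() {
  paste(rep(c("chest", "left-ankle", "right-wrist"), each = 3),
        "acc", c("x", "y", "z"), sep = "/")
}

#' Read a plain-text multi-channel sensor log
#'
#' Log dialect: whitespace-separated, no header, one row per sample at a
#' fixed rate, all declared signal channels in order, final column an integer
#' activity label. Timestamps are synthesized as `i / sampling_rate` because
#' the logs carry no time column.
#'
#' @param path Path to the log file.
#' @param column_map Channel layout, a list of [device_spec()]s; default
#'   [mhealth_column_map()] (23 signal columns + label).
#' @param sampling_rate Sampling rate in Hz; default 50.
#' @param subject_id,session_id Identifiers recorded in the metadata.
#' @return A [har_session()].
#' @export
read_mhealth_log <- function(path, column_map = mhealth_column_map(),
                             sampling_rate = 50, subject_id = "unknown",
                             session_id = basename(path)) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L) stop(sprintf("empty log file: %s", path))
  nm <- channel_names(column_map)
  ncols <- length(nm) + 1L
  toks <- strsplit(lines, "[ \t]+")
  nf <- lengths(toks)
  if (any(nf != ncols)) {
    bad <- which(nf != ncols)[1L]
    stop(sprintf("parse error at line %d of %s: expected %d columns, found %d",
                 line_no[bad], path, ncols, nf[bad]))
  }
  flat <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  if (anyNA(flat)) {
    bad <- ceiling(which(is.na(flat))[1L] / ncols)
    stop(sprintf("parse error at line %d of %s: non-numeric value",
                 line_no[bad], path))
  }
  m <- matrix(flat, ncol = ncols, byrow = TRUE)
  labels <- m[, ncols]
  if (any(labels != round(labels)))
    stop("label column must contain integers")
  n <- nrow(m)
  md <- har_metadata(session_id, subject_id,
                     start_time = 0, end_time = (n - 1) / sampling_rate,
                     sampling_rate = sampling_rate, devices = column_map)
  har_session(md, m[, -ncols, drop = FALSE], as.integer(labels))
}

#' Write a session as a plain-text sensor log
#'
#' One whitespace-delimited row per sample, channels in declared order, the
#' integer label last. Values are rendered with 17 significant digits so a
#' read/write roundtrip is lossless for doubles.
#'
#' @param session A [har_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mhealth_log <- function(session, path) {
  stopifnot(inherits(session, "har_session"))
  v <- session$values
  cols <- c(lapply(seq_len(ncol(v)), function(j) sprintf("%.17g", v[, j])),
            list(sprintf("%d", session$labels)))
  lines <- do.call(paste, cols)
  tryCatch(writeLines(lines, path),
           error = function(e) stop(sprintf("cannot write %s: %s",
                                            path, conditionMessage(e))))
  invisible(path)
}

#' Serialize a session to a JSON document
#'
#' The document has top-level keys `metadata` and `samples`; metadata (the
#' device/sensor/axis tree, units, interval and rate) appears exactly once,
#' not per sample, so the document grows linearly in the sample count with a
#' constant metadata overhead.
#'
#' @param session A [har_session()].
#' @return A length-1 character JSON document.
#' @export
session_to_json <- function(session) {
  stopifnot(inherits(session, "har_session"))
  md <- session$metadata
  doc <- list(
    metadata = list(
      session_id = md$session_id,
      subject_id = md$subject_id,
      start_time = md$start_time,
      end_time = md$end_time,
      sampling_rate = md$sampling_rate,
      devices = lapply(md$devices, function(d) list(
        device_name = d$device_name,
        sensors = lapply(d$sensors, function(s) list(
          sensor_type = s$sensor_type,
          units = s$units,
          axes = I(s$axes)
        ))
      ))
    ),
    samples = list(
      timestamps = I(session$timestamps),
      values = session$values,
      labels = I(session$labels)
    )
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                matrix = "rowmajor"))
}

#' Parse a JSON session document
#'
#' Inverse of [session_to_json()]; the roundtrip is exact for labels and
#' timestamps and lossless for channel values.
#'
#' @param txt JSON text produced by [session_to_json()].
#' @return A [har_session()].
#' @export
session_from_json <- function(txt) {
  doc <- jsonlite::fromJSON(txt, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  m <- doc$metadata
  devices <- lapply(m$devices, function(d) {
    device_spec(d$device_name, lapply(d$sensors, function(s) {
      sensor_spec(s$sensor_type, s$units, unlist(s$axes))
    }))
  })
  md <- har_metadata(m$session_id, m$subject_id, m$start_time, m$end_time,
                     m$sampling_rate, devices)
  nm <- channel_names(md)
  vals <- doc$samples$values
  if (length(vals) == 0L) {
    vals <- matrix(numeric(0), nrow = 0, ncol = length(nm))
  } else if (!is.matrix(vals)) {
    vals <- matrix(vals, nrow = 1)
  }
  har_session(md, vals, as.integer(unlist(doc$samples$labels)),
              timestamps = as.numeric(unlist(doc$samples$timestamps)))
}

#' Extract named channels from a session
#'
#' Returns a channel matrix: the requested columns in the requested order,
#' with per-row labels and the sampling rate carried along. Values are copied
#' verbatim, never transformed.
#'
#' @param session A [har_session()].
#' @param channels Character vector of declared channel names; default all.
#' @return An object of class `channel_matrix` with fields `values`
#'   (samples x channels matrix), `channel_names`, `labels`, `sampling_rate`.
#' @export
select_channels <- function(session, channels = NULL) {
  stopifnot(inherits(session, "har_session"))
  nm <- colnames(session$values)
  if (is.null(channels)) channels <- nm
  missing <- setdiff(channels, nm)
  if (length(missing))
    stop(sprintf("unknown channel name(s): %s",
                 paste(missing, collapse = ", ")))
  channel_matrix(session$values[, channels, drop = FALSE],
                 session$labels, session$metadata$sampling_rate)
}

#' Construct a channel matrix
#'
#' @param values Numeric matrix, samples x channels, with column names.
#' @param labels Integer labels, one per row.
#' @param sampling_rate Hz.
#' @return An object of class `channel_matrix`.
#' @export
channel_matrix <- function(values, labels, sampling_rate) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("ch", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values))) stop("channel names must be unique")
  if (nrow(values) != length(labels))
    stop("labels must have one entry per row")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  structure(list(values = values, channel_names = colnames(values),
                 labels = as.integer(labels),
                 sampling_rate = as.numeric(sampling_rate)),
            class = "channel_matrix")
}

#' @export
print.channel_matrix <- function(x, ...) {
  cat(sprintf("<channel_matrix> %d samples x %d channels @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$sampling_rate))
  cat("  channels:", paste(utils::head(x$channel_names, 6), collapse = ", "),
      if (length(x$channel_names) > 6) "..." else "", "\n")
  invisible(x)
}
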