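#' Activity signal signatures
#'
#' Each of the 12 activities is modelled, per device, as a gravity component
#' (a unit orientation vector scaled by 9.81 m/s^2) plus a per-axis
#' sinusoidal oscillation (amplitude in m/s^2, a fundamental frequency in Hz
#' shared by the device's axes, per-axis phase) plus Gaussian noise. The
#' defaults encode the qualitative structure of the activity set:
#'
#' * the static postures L1 standing, L2 sitting, L3 lying differ only in
#'   the gravity orientation of the devices (frequency 0);
#' * the locomotion family shares its waveform shape with cadence and
#'   amplitude increasing from L4 walking (1.5 Hz) through L10 jogging
#'   (2.5 Hz) to L11 running (3.0 Hz), deliberately making these the most
#'   confusable classes;
#' * L6 waist bends and L8 knees bending share a low-frequency trunk sway
#'   component, the other characteristically confusable pair.
#'
#' Amplitudes and cadences are declared constants chosen to be plausible
#' for body-worn accelerometry, not estimates of any particular recording.
#'
#' @return Named list of 12 signatures (`"1"` .. `"12"`), each with fields
#'   `code`, `name`, `noise_sd` and per-device `gravity` (unit 3-vector),
#'   `amp` (3), `freq` (Hz), `phase` (3).
#' @export
default_signatures <- function() {
  unit <- function(v) v / sqrt(sum(v^2))
  dev <- function(gravity, amp = c(0, 0, 0), freq = 0,
                  phase = c(0, pi / 3, 2 * pi / 3)) {
    list(gravity = unit(gravity), amp = amp, freq = freq, phase = phase)
  }
  sig <- function(code, name, chest, ankle, wrist, noise_sd) {
    list(code = code, name = name, noise_sd = noise_sd,
         devices = list(chest = chest, `left-ankle` = ankle,
                        `right-wrist` = wrist))
  }
  upright <- c(0, 0, 1)
  sigs <- list(
    sig(1L, "Standing still",
        dev(upright), dev(upright), dev(upright), 0.25),
    sig(2L, "Sitting and relaxing",
        dev(c(0.3, 0, 1)), dev(c(0.6, 0, 0.8)), dev(c(1, 0, 0.35)), 0.25),
    sig(3L, "Lying down",
        dev(c(1, 0, 0)), dev(c(1, 0, 0.1)), dev(c(0.9, 0.3, 0.2)), 0.25),
    sig(4L, "Walking",
        dev(upright, c(0.8, 0.3, 1.0), 1.5),
        dev(upright, c(3.0, 1.0, 2.5), 1.5),
        dev(upright, c(1.0, 0.5, 0.8), 1.5), 0.5),
    sig(5L, "Climbing stairs",
        dev(c(0.18, 0, 1), c(1.4, 0.5, 2.0), 1.2),
        dev(c(0.12, 0, 1), c(3.8, 1.3, 4.0), 1.2),
        dev(upright, c(1.2, 0.7, 1.2), 1.2), 0.5),
    sig(6L, "Waist bends forward",
        dev(c(0.5, 0, 0.9), c(4.0, 0.5, 3.0), 0.4),
        dev(upright, c(0.3, 0.2, 0.3), 0.4),
        dev(c(0.4, 0.1, 0.9), c(1.5, 0.5, 1.2), 0.4), 0.4),
    sig(7L, "Frontal elevation of arms",
        dev(upright, c(0.4, 0.2, 0.4), 0.5),
        dev(upright, c(0.2, 0.1, 0.2), 0.5),
        dev(c(0.5, 0, 0.85), c(5.0, 1.0, 4.0), 0.5), 0.4),
    sig(8L, "Knees bending",
        dev(c(0.35, 0, 0.95), c(2.5, 0.4, 2.8), 0.5),
        dev(c(0.2, 0, 1), c(1.5, 0.5, 1.8), 0.5, c(1, 1 + pi / 3, 2)),
        dev(c(0.3, 0.1, 0.95), c(1.0, 0.4, 0.8), 0.5), 0.4),
    sig(9L, "Cycling",
        dev(c(0.45, 0, 0.9), c(0.4, 0.2, 0.4), 1.0),
        dev(c(0.5, 0, 0.85), c(2.5, 0.8, 2.5), 1.0),
        dev(c(0.8, 0, 0.6), c(0.5, 0.3, 0.4), 1.0), 0.45),
    sig(10L, "Jogging",
        dev(upright, c(1.8, 0.6, 2.2), 2.5),
        dev(upright, c(5.0, 1.5, 4.6), 2.5),
        dev(upright, c(2.0, 1.0, 1.8), 2.5), 0.8),
    sig(11L, "Running",
        dev(upright, c(2.1, 0.7, 2.5), 3.0),
        dev(upright, c(5.8, 1.7, 5.3), 3.0),
        dev(upright, c(2.3, 1.15, 2.1), 3.0), 0.8),
    sig(12L, "Jump front & back",
        dev(upright, c(2.0, 0.8, 5.0), 0.9),
        dev(upright, c(4.0, 1.5, 6.0), 0.9),
        dev(upright, c(2.5, 1.0, 3.0), 0.9), 0.6)
  )
  names(sigs) <- as.character(1:12)
  sigs
}

#' Subject profile
#'
#' Between-subject variability is modelled as two positive multipliers
#' drawn once per subject: `amplitude_scale` rescales all oscillation
#' amplitudes and `cadence_scale` all fundamental frequencies.
#'
#' @param subject_id Identifier string.
#' @param amplitude_scale,cadence_scale Positive multipliers.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, amplitude_scale = 1,
                            cadence_scale = 1) {
  if (amplitude_scale <= 0 || cadence_scale <= 0)
    stop("subject scales must be positive")
  structure(list(subject_id = as.character(subject_id),
                 amplitude_scale = amplitude_scale,
                 cadence_scale = cadence_scale),
            class = "subject_profile")
}

#' Activity schedule
#'
#' An ordered sequence of (activity code, duration) pairs, optionally with
#' null-labelled gaps (label 0) between consecutive activities so that the
#' online protocol's transition exclusion can be exercised.
#'
#' @param activities Integer activity codes (1..12).
#' @param duration_seconds Duration of each activity bout; recycled. The
#'   runtime protocol this generator emulates used 30 s per activity.
#' @param gap_seconds Null-labelled gap inserted between bouts (0 = none).
#' @return Data frame with columns `activity`, `duration`.
#' @export
har_schedule <- function(activities = 1:12, duration_seconds = 30,
                         gap_seconds = 0) {
  if (any(duration_seconds <= 0)) stop("durations must be positive")
  dur <- rep_len(duration_seconds, length(activities))
  rows <- list()
  for (i in seq_along(activities)) {
    if (gap_seconds > 0 && i > 1)
      rows[[length(rows) + 1L]] <- data.frame(activity = 0L,
                                              duration = gap_seconds)
    rows[[length(rows) + 1L]] <- data.frame(activity = activities[i],
                                            duration = dur[i])
  }
  do.call(rbind, rows)
}

#' Generate one synthetic recording session
#'
#' Produces a full session in the default 23-channel layout
#' ([mhealth_column_map()]): per acceleration axis, gravity component +
#' amplitude-scaled sinusoid + Gaussian noise, per the activity signatures;
#' gyroscope and magnetometer channels are labelled filler signals
#' (a phase-shifted oscillation and a noisy orientation constant); the ECG
#' leads carry a fixed quasi-periodic placeholder waveform, never used for
#' recognition. Null-labelled gaps get an upright resting signal with
#' elevated noise. Deterministic given `seed`.
#'
#' @param profile A [subject_profile()].
#' @param schedule A [har_schedule()] data frame.
#' @param sampling_rate Hz; default 50.
#' @param seed Integer seed.
#' @param signatures Activity signatures; default [default_signatures()].
#' @param noise_sd Override for the per-activity noise level (e.g. 0 for a
#'   noiseless session); `NULL` uses each signature's own.
#' @return A [har_session()].
#' @export
generate_session <- function(profile, schedule = har_schedule(),
                             sampling_rate = 50, seed = 1L,
                             signatures = default_signatures(),
                             noise_sd = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  fs <- sampling_rate
  known <- c(0L, vapply(signatures, `[[`, integer(1), "code"))
  if (!all(schedule$activity %in% known))
    stop(sprintf("unknown activity code(s): %s",
                 paste(setdiff(schedule$activity, known), collapse = ", ")))
  seg_n <- round(schedule$duration * fs)
  labels <- rep(schedule$activity, seg_n)
  n <- length(labels)
  t <- (seq_len(n) - 1) / fs
  devices <- mhealth_column_map()
  nm <- channel_names(devices)
  values <- matrix(0, n, length(nm), dimnames = list(NULL, nm))

  rest <- list(gravity = c(0, 0, 1), amp = c(0, 0, 0), freq = 0,
               phase = c(0, 0, 0))
  set.seed(seed)
  seg_end <- cumsum(seg_n)
  seg_start <- c(0L, seg_end[-length(seg_end)])
  for (s in seq_len(nrow(schedule))) {
    rows <- (seg_start[s] + 1L):seg_end[s]
    code <- schedule$activity[s]
    if (code == 0L) {
      sg <- list(noise_sd = 0.8,
                 devices = list(chest = rest, `left-ankle` = rest,
                                `right-wrist` = rest))
    } else sg <- signatures[[as.character(code)]]
    sd_here <- if (is.null(noise_sd)) sg$noise_sd else noise_sd
    tt <- t[rows]
    for (dname in names(sg$devices)) {
      d <- sg$devices[[dname]]
      freq <- d$freq * profile$cadence_scale
      for (ax in 1:3) {
        ch <- sprintf("%s/acc/%s", dname, c("x", "y", "z")[ax])
        base <- d$gravity[ax] * 9.81 +
          d$amp[ax] * profile$amplitude_scale *
            sin(2 * pi * freq * tt + d$phase[ax])
        values[rows, ch] <- base +
          if (sd_here > 0) stats::rnorm(length(rows), 0, sd_here) else 0
      }
      if (dname != "chest") {          # gyro/mag filler channels
        for (ax in 1:3) {
          gch <- sprintf("%s/gyro/%s", dname, c("x", "y", "z")[ax])
          mch <- sprintf("%s/mag/%s", dname, c("x", "y", "z")[ax])
          values[rows, gch] <- 20 * d$amp[ax] * profile$amplitude_scale *
            cos(2 * pi * freq * tt + d$phase[ax]) +
            if (sd_here > 0) stats::rnorm(length(rows), 0, 5 * sd_here)
            else 0
          values[rows, mch] <- 40 * d$gravity[ax] +
            if (sd_here > 0) stats::rnorm(length(rows), 0, sd_here) else 0
        }
      }
    }
    # fixed quasi-periodic ECG placeholder, not subject- or activity-coded
    values[rows, "chest/ecg/lead1"] <-
      0.6 * sin(2 * pi * 1.1 * tt) + 0.25 * sin(2 * pi * 3.3 * tt + 0.4)
    values[rows, "chest/ecg/lead2"] <-
      0.5 * sin(2 * pi * 1.1 * tt + 0.8) + 0.2 * sin(2 * pi * 2.2 * tt)
  }
  md <- har_metadata(sprintf("synthetic-%s", profile$subject_id),
                     profile$subject_id, 0, (n - 1) / fs, fs, devices)
  har_session(md, values, labels)
}

#' Generate a multi-subject synthetic dataset
#'
#' Draws one [subject_profile()] per subject — `amplitude_scale ~
#' lognormal(0, 0.1)`, `cadence_scale ~ lognormal(0, 0.05)` — and generates
#' one session per subject. All randomness flows from the single root seed:
#' profiles are drawn first, then session `i` uses seed
#' `seed + 1009 * i`, so sessions are reproducible and pairwise distinct.
#'
#' @param n_subjects Number of subjects (>= 1); the recorded cohort this
#'   generator emulates had 10.
#' @param schedule,sampling_rate,signatures,noise_sd As in
#'   [generate_session()].
#' @param seed Root seed.
#' @return List of [har_session()]s with subject ids `"subject01"`, ...
#' @export
generate_dataset <- function(n_subjects = 10, schedule = har_schedule(),
                             sampling_rate = 50, seed = 1L,
                             signatures = default_signatures(),
                             noise_sd = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  set.seed(seed)
  amp <- stats::rlnorm(n_subjects, 0, 0.1)
  cad <- stats::rlnorm(n_subjects, 0, 0.05)
  lapply(seq_len(n_subjects), function(i) {
    p <- subject_profile(sprintf("subject%02d", i), amp[i], cad[i])
    generate_session(p, schedule, sampling_rate,
                     seed = seed + 1009L * i,
                     signatures = signatures, noise_sd = noise_sd)
  })
}
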