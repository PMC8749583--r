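#' Synthesise a multi-channel surface-EMG recording
#'
#' Generates a protocol-faithful synthetic recording: each channel is a
#' zero-mean stochastic carrier band-limited to `carrier_band` (filtered
#' Gaussian white noise, standardised to unit RMS), amplitude-modulated by
#' a trapezoidal envelope that sits at the channel's resting amplitude
#' during rest and rises to the gesture-specific amplitude during
#' contraction. Muscle activation starts a random latency after each
#' gesture command (drawn once per gesture block, shared by the three
#' channels), ramps up over `ramp_s`, holds for the commanded gesture
#' duration, and ramps back down. A 60 Hz sinusoid of amplitude
#' `line_amp` is added last to emulate mains pickup.
#'
#' Identical `(schedule, profile)` pairs produce bit-identical recordings.
#'
#' @param schedule An `emg_schedule`; every non-rest block label must have a
#'   row in `profile$gesture_gain`.
#' @param profile An `emg_profile`.
#' @param carrier_band Length-2 passband of the carrier noise, Hz.
#' @param carrier_order Butterworth order used to shape the carrier.
#' @return An object of class `emg_recording`: list with `samples`
#'   (3 x n matrix), `fs`, `schedule`, `subject_id`, `envelope`
#'   (3 x n matrix of the applied modulation, kept for diagnostics).
#' @export
synthesize_recording <- function(schedule, profile,
                                 carrier_band = c(20, 450),
                                 carrier_order = 4) {
  stopifnot(inherits(schedule, "emg_schedule"), inherits(profile, "emg_profile"))
  missing_g <- setdiff(schedule$gestures, rownames(profile$gesture_gain))
  if (length(missing_g))
    stop("profile lacks gains for gesture(s): ", paste(missing_g, collapse = ", "))
  n <- schedule$n_samples
  fs <- schedule$fs
  set.seed(profile$seed)

  blk <- schedule$blocks
  gesture_rows <- which(blk$label != rest_label())
  latencies <- stats::runif(length(gesture_rows),
                            profile$onset_latency_s[1],
                            profile$onset_latency_s[2])

  sos <- butter_sos(filter_spec("bandpass", carrier_order,
                                carrier_band[1], carrier_band[2]), fs)
  ramp_n <- round(profile$ramp_s * fs)
  env <- matrix(rep(profile$rest_gain, n), nrow = 3)
  samples <- matrix(0, nrow = 3, ncol = n)
  tvec <- (seq_len(n) - 1) / fs
  line <- profile$line_amp * sin(2 * pi * 60 * tvec)

  for (ch in 1:3) {
    carrier <- sos_filter(sos, stats::rnorm(n))
    carrier <- carrier / stats::sd(carrier)
    for (k in seq_along(gesture_rows)) {
      i <- gesture_rows[k]
      g <- blk$label[i]
      onset <- blk$start_sample[i] + round(latencies[k] * fs)
      hold_n <- blk$n_samples[i]           # activated for the commanded duration
      gain <- profile$gesture_gain[g, ch]
      env[ch, ] <- add_trapezoid(env[ch, ], onset, hold_n, ramp_n,
                                 profile$rest_gain[ch], gain)
    }
    samples[ch, ] <- carrier * env[ch, ] + line
  }
  structure(list(samples = samples, fs = fs, schedule = schedule,
                 subject_id = profile$subject_id, envelope = env,
                 filtered = FALSE),
            class = "emg_recording")
}

# Overwrite env with a trapezoid: linear rise over ramp_n samples ending at
# full gain at `onset + ramp_n`, hold for hold_n, linear fall back to rest.
add_trapezoid <- function(env, onset, hold_n, ramp_n, rest, gain) {
  n <- length(env)
  clip <- function(i) pmin(pmax(i, 1L), n)
  if (ramp_n > 0) {
    idx <- onset:(onset + ramp_n - 1L)
    val <- rest + (gain - rest) * seq_len(ramp_n) / ramp_n
    keep <- idx >= 1 & idx <= n
    env[idx[keep]] <- val[keep]
  }
  hi <- (onset + ramp_n):(onset + hold_n - 1L)
  hi <- hi[hi >= 1 & hi <= n]
  env[hi] <- gain
  if (ramp_n > 0) {
    idx <- (onset + hold_n):(onset + hold_n + ramp_n - 1L)
    val <- gain + (rest - gain) * seq_len(ramp_n) / ramp_n
    keep <- idx >= 1 & idx <= n
    env[idx[keep]] <- val[keep]
  }
  env
}

#' Write a recording to delimited text
#'
#' Columns: `time_s, ch1, ch2, ch3, command` (the commanded block label per
#' sample), comma separated with a header row.
#'
#' @param recording An `emg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  n <- ncol(recording$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$fs,
                   ch1 = recording$samples[1, ],
                   ch2 = recording$samples[2, ],
                   ch3 = recording$samples[3, ],
                   command = command_labels(recording$schedule))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV file path.
#' @param schedule Optional `emg_schedule` to attach; if supplied, its
#'   length and per-sample command labels must match the file.
#' @param subject_id Identifier for the returned recording.
#' @return An `emg_recording` (with `schedule = NULL` when none is given).
#' @export
read_recording <- function(path, schedule = NULL, subject_id = "s1") {
  df <- utils::read.csv(path)
  need <- c("time_s", "ch1", "ch2", "ch3", "command")
  if (!all(need %in% names(df)))
    stop("recording file must have columns: ", paste(need, collapse = ", "))
  fs <- round(1 / stats::median(diff(df$time_s)))
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "emg_schedule"))
    if (schedule$n_samples != nrow(df) ||
        !identical(command_labels(schedule), as.character(df$command)))
      stop("supplied schedule does not match the file's command column")
    fs <- schedule$fs
  }
  samples <- unname(t(as.matrix(df[, c("ch1", "ch2", "ch3")])))
  structure(list(samples = samples,
                 fs = fs, schedule = schedule, subject_id = subject_id,
                 envelope = NULL, filtered = FALSE),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("<emg_recording>\n")
  cat(sprintf("  subject %s: 3 x %d samples at %g Hz (%.1f s)%s\n",
              x$subject_id, ncol(x$samples), x$fs, ncol(x$samples) / x$fs,
              if (isTRUE(x$filtered)) ", filtered" else ""))
  invisible(x)
}
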