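#' Default per-gesture carrier amplitudes
#'
#' A 9 x 3 matrix of carrier amplitudes (arbitrary units, gestures in rows,
#' channels in columns). Each gesture activates at least one channel well
#' above the resting baseline and no two gestures share the same
#' three-channel amplitude pattern, which is what makes the ten classes
#' separable from amplitude-sensitive features.
#'
#' @param gain Peak amplitude of the dominant channel relative to a unit
#'   resting baseline. The default of 5 gives a strongly supra-threshold
#'   contraction.
#' @return Numeric matrix with `emg_gestures()` rownames and columns
#'   `ch1:ch3`.
#' @export
default_gesture_gains <- function(gain = 5) {
  pat <- rbind(
    rock       = c(1.0, 0.4, 0.2),
    scissors   = c(0.2, 1.0, 0.4),
    paper      = c(0.4, 0.2, 1.0),
    one        = c(1.0, 1.0, 0.2),
    three      = c(0.2, 1.0, 1.0),
    four       = c(1.0, 0.2, 1.0),
    good       = c(0.8, 0.6, 0.2),
    okay       = c(0.2, 0.8, 0.6),
    finger_gun = c(0.6, 0.2, 0.8))
  m <- pat * gain
  colnames(m) <- paste0("ch", 1:3)
  m
}

#' Describe one simulated subject
#'
#' Bundles everything subject-specific about a synthetic recording: the
#' per-(gesture, channel) contraction amplitudes, the resting baseline
#' amplitude, the distribution of the delay between a gesture command and
#' actual muscle activation, the envelope rise/fall time, the mains
#' interference amplitude and the random seed.
#'
#' @param gesture_gain Matrix (gestures x 3 channels) of carrier amplitudes
#'   during contraction; rownames are gesture names.
#' @param rest_gain Length-3 positive baseline amplitude per channel.
#' @param onset_latency_s Length-2 bounds (min, max) of the uniform onset
#'   latency in seconds.
#' @param ramp_s Envelope linear rise/fall time, seconds.
#' @param line_amp Amplitude of the additive 60 Hz mains component.
#' @param seed Integer seed controlling all randomness in the recording.
#' @param subject_id Identifier carried through to recordings and tables.
#' @return An object of class `emg_profile`.
#' @export
subject_profile <- function(gesture_gain = default_gesture_gains(),
                            rest_gain = rep(1, 3),
                            onset_latency_s = c(0, 0.3),
                            ramp_s = 0.2, line_amp = 0.2,
                            seed = 1L, subject_id = "s1") {
  gesture_gain <- as.matrix(gesture_gain)
  if (ncol(gesture_gain) != 3) stop("'gesture_gain' must have 3 channel columns")
  if (is.null(rownames(gesture_gain))) stop("'gesture_gain' needs gesture rownames")
  if (length(rest_gain) != 3 || any(rest_gain <= 0))
    stop("'rest_gain' must be 3 positive values")
  ok <- apply(gesture_gain >= matrix(rest_gain, nrow(gesture_gain), 3, byrow = TRUE),
              1, any)
  if (!all(ok))
    stop("every gesture must reach at least the resting amplitude on one channel")
  if (anyDuplicated(apply(gesture_gain, 1, paste, collapse = ",")))
    stop("gesture amplitude patterns must be distinct across gestures")
  if (length(onset_latency_s) != 2 || any(onset_latency_s < 0) ||
      onset_latency_s[1] > onset_latency_s[2])
    stop("'onset_latency_s' must be non-negative (min, max) bounds")
  if (ramp_s < 0 || line_amp < 0) stop("'ramp_s' and 'line_amp' must be >= 0")
  structure(list(gesture_gain = gesture_gain, rest_gain = rest_gain,
                 onset_latency_s = onset_latency_s, ramp_s = ramp_s,
                 line_amp = line_amp, seed = as.integer(seed),
                 subject_id = subject_id),
            class = "emg_profile")
}

#' Simulate a cohort of subjects
#'
#' Draws `n_subjects` subject profiles around `base_profile` by perturbing
#' every contraction and resting amplitude with independent multiplicative
#' log-normal noise (`sdlog = variability`), then synthesises one recording
#' per subject under `schedule`. Log-normal perturbation keeps amplitudes
#' strictly positive, mimicking inter-subject differences in muscle bulk,
#' skin impedance and electrode coupling.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param base_profile Template `emg_profile`.
#' @param variability Fractional spread (log-sd) of the amplitude
#'   perturbations; 0 reproduces `base_profile` for everyone.
#' @param seed Integer seed for the cohort.
#' @param schedule `emg_schedule` used for every subject.
#' @return List of length `n_subjects`; each element has `profile` and
#'   `recording`.
#' @export
make_cohort <- function(n_subjects, base_profile = subject_profile(),
                        variability = 0.2, seed = 1L,
                        schedule = build_schedule()) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("'n_subjects' must be >= 1")
  if (variability < 0) stop("'variability' must be >= 0")
  n_subjects <- as.integer(n_subjects)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sub_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    set.seed(sub_seed)
    gg <- base_profile$gesture_gain *
      matrix(stats::rlnorm(length(base_profile$gesture_gain),
                           sdlog = variability),
             nrow(base_profile$gesture_gain))
    rg <- base_profile$rest_gain * stats::rlnorm(3, sdlog = variability)
    prof <- subject_profile(gesture_gain = gg, rest_gain = rg,
                            onset_latency_s = base_profile$onset_latency_s,
                            ramp_s = base_profile$ramp_s,
                            line_amp = base_profile$line_amp,
                            seed = sub_seed,
                            subject_id = sprintf("s%02d", i))
    out[[i]] <- list(profile = prof,
                     recording = synthesize_recording(schedule, prof))
  }
  out
}
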