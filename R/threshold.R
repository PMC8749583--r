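#' Baseline calibration for the activation threshold
#'
#' For every (gesture, round, channel), measures the peak magnitude of the
#' filtered signal over the first `baseline_span_s` seconds of the round's
#' leading rest block (skipping `skip_s` at the start so the filter startup
#' transient cannot inflate the baseline). The activation threshold on
#' channel `c` is then `lambda * Baseline_max[c]`, where `Baseline_max[c]`
#' is the largest per-round baseline observed on that channel, and the
#' admissible range of the dimensionless coefficient `lambda` is
#' `[1, lambda_max]`, with `lambda_max` the ratio of the largest to the
#' smallest per-round baseline.
#'
#' @param recording A (filtered) `emg_recording` with a schedule whose
#'   rounds each begin with a rest block of at least `baseline_span_s`.
#' @param baseline_span_s Length of the baseline span, seconds.
#' @param skip_s Initial seconds of each round excluded from the baseline.
#' @return An object of class `emg_calibration`: `baseline_max`
#'   (3-d array gesture x round x channel), `per_round` (matrix of
#'   per-(gesture, round) maxima across channels), `channel_base`
#'   (length-3, the per-channel threshold base), `lambda_max`,
#'   `baseline_spans` (data frame of the sample ranges used).
#' @export
compute_baseline_max <- function(recording, baseline_span_s = 4,
                                 skip_s = 0.25) {
  stopifnot(inherits(recording, "emg_recording"))
  sch <- recording$schedule
  if (is.null(sch)) stop("recording carries no schedule")
  blk <- sch$blocks
  rb <- sch$round_boundaries
  if (sch$rest_s < baseline_span_s)
    stop("rounds must begin with a rest block of at least the baseline span")
  span_n <- round(baseline_span_s * sch$fs)
  skip_n <- round(skip_s * sch$fs)
  gestures <- sch$gestures
  bm <- array(NA_real_, dim = c(length(gestures), max(rb$round), 3),
              dimnames = list(gestures, NULL, paste0("ch", 1:3)))
  spans <- rb[, c("gesture", "round")]
  spans$from <- rb$start_sample + skip_n
  spans$to <- rb$start_sample + span_n - 1L
  for (i in seq_len(nrow(rb))) {
    lead <- blk$label[blk$start_sample == rb$start_sample[i]]
    if (length(lead) != 1L || lead != rest_label())
      stop("round does not begin with a rest block")
    seg <- recording$samples[, spans$from[i]:spans$to[i], drop = FALSE]
    bm[rb$gesture[i], rb$round[i], ] <- apply(abs(seg), 1, max)
  }
  per_round <- apply(bm, c(1, 2), max)
  if (any(per_round <= 0, na.rm = TRUE))
    stop("baseline maximum is zero: threshold would not be positive")
  structure(list(
    baseline_max = bm,
    per_round = per_round,
    channel_base = apply(bm, 3, max, na.rm = TRUE),
    lambda_max = max(per_round, na.rm = TRUE) / min(per_round, na.rm = TRUE),
    baseline_spans = spans,
    baseline_span_s = baseline_span_s, skip_s = skip_s),
    class = "emg_calibration")
}

#' Per-channel activation thresholds
#' @param calibration An `emg_calibration`.
#' @param lambda Dimensionless coefficient in `[1, lambda_max]`.
#' @return Length-3 numeric vector of amplitude thresholds.
#' @export
threshold_values <- function(calibration, lambda) {
  stopifnot(inherits(calibration, "emg_calibration"))
  if (lambda < 1) stop("'lambda' must be >= 1")
  lambda * calibration$channel_base
}

#' Choose the activation-threshold coefficient
#'
#' Sweeps `lambda` upward over `grid` and returns the smallest value for
#' which no threshold crossing occurs anywhere in the commanded rest
#' portions of the recording (excluding a `guard_s` tail after each gesture
#' block, where the envelope is still decaying, and `skip_s` at each round
#' start). This maximises onset sensitivity subject to zero rest-state
#' false activations. If every grid value produces a rest crossing,
#' `lambda_max` is returned with a warning.
#'
#' @param calibration An `emg_calibration` from the same recording.
#' @param recording The filtered `emg_recording`.
#' @param grid Increasing lambda values within `[1, lambda_max]`; default
#'   25 evenly spaced values.
#' @param guard_s Seconds after each gesture block excluded from the rest
#'   check (covers onset latency plus envelope fall time).
#' @return Selected lambda (scalar).
#' @export
select_lambda <- function(calibration, recording, grid = NULL, guard_s = 1) {
  stopifnot(inherits(calibration, "emg_calibration"),
            inherits(recording, "emg_recording"))
  if (is.null(grid)) {
    grid <- unique(seq(1, max(1, calibration$lambda_max), length.out = 25))
  }
  if (length(grid) == 0) stop("'grid' must be non-empty")
  if (any(grid < 1) || any(grid > calibration$lambda_max + 1e-9))
    stop("'grid' values must lie in [1, lambda_max]")
  grid <- sort(grid)
  sch <- recording$schedule
  rest_mask <- rest_check_mask(sch, guard_s, calibration$skip_s)
  peak <- apply(abs(recording$samples[, rest_mask, drop = FALSE]), 1, max)
  for (lam in grid) {
    if (!any(peak > threshold_values(calibration, lam)))
      return(lam)
  }
  warning("all grid values produce rest-span crossings; returning lambda_max")
  calibration$lambda_max
}

# Logical mask of rest samples eligible for the false-activation check:
# commanded rest inside round spans, minus guard_s after each gesture block
# and skip_s after each round start.
rest_check_mask <- function(schedule, guard_s, skip_s) {
  n <- schedule$n_samples
  mask <- rep(FALSE, n)
  rb <- schedule$round_boundaries
  for (i in seq_len(nrow(rb)))
    mask[rb$start_sample[i]:rb$end_sample[i]] <- TRUE
  mask <- mask & (command_labels(schedule) == rest_label())
  guard_n <- round(guard_s * schedule$fs)
  skip_n <- round(skip_s * schedule$fs)
  blk <- schedule$blocks
  for (i in which(blk$label != rest_label())) {
    from <- blk$start_sample[i] + blk$n_samples[i]
    if (guard_n > 0 && from <= n)
      mask[from:min(n, from + guard_n - 1L)] <- FALSE
  }
  if (skip_n > 0)
    for (i in seq_len(nrow(rb)))
      mask[rb$start_sample[i]:min(n, rb$start_sample[i] + skip_n - 1L)] <- FALSE
  mask
}

#' Detect muscle-activation onsets and build the activated-state timeline
#'
#' For every commanded gesture block, each channel is scanned from the
#' rest-to-gesture command boundary for the first sample whose magnitude
#' exceeds that channel's threshold; the earliest crossing across the three
#' channels is the activation point. The signal is taken to be in the
#' activated state for `activation_s` seconds from the activation point
#' (truncated at the recording end). Blocks with no crossing contribute no
#' activated samples.
#'
#' @param recording Filtered `emg_recording`.
#' @param calibration An `emg_calibration`.
#' @param lambda Threshold coefficient (e.g. from [select_lambda()]).
#' @param activation_s Activated-state duration from onset; defaults to the
#'   schedule's commanded gesture duration.
#' @return An object of class `emg_timeline`: `activated` (logical per
#'   sample), `points` (data frame: `gesture`, `round`, `block_start`,
#'   `activation_sample`, `channel`), `activation_s`, `lambda`.
#' @export
detect_activation <- function(recording, calibration, lambda,
                              activation_s = NULL) {
  stopifnot(inherits(recording, "emg_recording"),
            inherits(calibration, "emg_calibration"))
  sch <- recording$schedule
  if (is.null(activation_s)) activation_s <- sch$gesture_s
  thr <- threshold_values(calibration, lambda)
  n <- sch$n_samples
  act_n <- round(activation_s * sch$fs)
  own <- round_ownership(sch)
  activated <- rep(FALSE, n)
  blk <- sch$blocks
  pts <- list()
  for (i in which(blk$label != rest_label())) {
    span <- blk$start_sample[i]:(blk$start_sample[i] + blk$n_samples[i] - 1L)
    first <- rep(NA_integer_, 3)
    for (ch in 1:3) {
      hit <- which(abs(recording$samples[ch, span]) > thr[ch])
      if (length(hit)) first[ch] <- span[hit[1]]
    }
    if (all(is.na(first))) next
    ch_win <- which.min(first)
    onset <- first[ch_win]
    activated[onset:min(n, onset + act_n - 1L)] <- TRUE
    pts[[length(pts) + 1]] <- data.frame(
      gesture = blk$label[i], round = own$round[blk$start_sample[i]],
      block_start = blk$start_sample[i], activation_sample = onset,
      channel = ch_win)
  }
  structure(list(activated = activated,
                 points = if (length(pts)) do.call(rbind, pts) else
                   data.frame(gesture = character(), round = integer(),
                              block_start = integer(),
                              activation_sample = integer(),
                              channel = integer()),
                 activation_s = activation_s, lambda = lambda),
            class = "emg_timeline")
}

#' Ideal (noise-free) activation timeline
#'
#' The timeline a perfect detector would produce: activated exactly during
#' the commanded gesture blocks. Useful for protocol arithmetic and as a
#' reference in tests.
#'
#' @param schedule An `emg_schedule`.
#' @return An `emg_timeline`.
#' @export
ideal_timeline <- function(schedule) {
  stopifnot(inherits(schedule, "emg_schedule"))
  activated <- command_labels(schedule) != rest_label()
  structure(list(activated = activated,
                 points = NULL, activation_s = schedule$gesture_s,
                 lambda = NA_real_),
            class = "emg_timeline")
}

#' Segment a recording round-by-round and label every window
#'
#' Windows are enumerated inside each (gesture, round) span of the
#' schedule, so no window straddles two rounds. A window is labelled with
#' the round's gesture when more than half of its samples are in the
#' activated state, and with the rest class otherwise.
#'
#' @param timeline An `emg_timeline` (from [detect_activation()] or
#'   [ideal_timeline()]).
#' @param schedule The `emg_schedule` the timeline refers to.
#' @param spec An `emg_windowing`.
#' @param subject_id Identifier copied into every row.
#' @return Data frame with one row per window: `subject`, `gesture` (the
#'   round's gesture), `round`, `start_sample`, `label`.
#' @export
annotate_windows <- function(timeline, schedule, spec = windowing_spec(),
                             subject_id = "s1") {
  stopifnot(inherits(timeline, "emg_timeline"),
            inherits(schedule, "emg_schedule"))
  ws <- window_samples(spec, schedule$fs)
  W <- ws[["window"]]
  cact <- c(0, cumsum(timeline$activated))  # cact[i + 1] = activated in 1..i
  rb <- schedule$round_boundaries
  out <- vector("list", nrow(rb))
  for (i in seq_len(nrow(rb))) {
    span_len <- rb$end_sample[i] - rb$start_sample[i] + 1L
    starts <- rb$start_sample[i] - 1L +
      segment_windows(span_len, spec, schedule$fs)
    n_act <- cact[starts + W] - cact[starts]
    out[[i]] <- data.frame(
      subject = subject_id, gesture = rb$gesture[i], round = rb$round[i],
      start_sample = starts,
      label = ifelse(n_act > W / 2, rb$gesture[i], rest_label()))
  }
  do.call(rbind, out)
}
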