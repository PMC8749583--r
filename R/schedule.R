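#' The nine non-rest gestures
#'
#' Canonical names of the nine non-rest hand/finger gestures recognised by
#' the pipeline. The rest state (`"rest"`) is the tenth class.
#'
#' @return Character vector of length 9.
#' @export
emg_gestures <- function() {
  c("rock", "scissors", "paper", "one", "three", "four",
    "good", "okay", "finger_gun")
}

#' Label used for the rest class
#' @return The string `"rest"`.
#' @export
rest_label <- function() "rest"

#' Build a commanded rest/gesture recording schedule
#'
#' Constructs the block schedule under which a recording is (or is simulated
#' to be) acquired. For every gesture, each round consists of
#' `sets_per_round` repetitions of a rest block followed by a gesture block;
#' consecutive rounds (and consecutive gestures) are separated by a longer
#' rest block. The defaults reproduce the acquisition protocol used
#' throughout the package: 9 gestures x 4 rounds x 5 sets of (5 s rest,
#' 5 s gesture), with 10 s rest between rounds, sampled at 2000 Hz.
#'
#' @param gestures Character vector of non-rest gesture names.
#' @param rounds Number of rounds per gesture.
#' @param sets_per_round Number of (rest, gesture) sets in one round.
#' @param rest_s Duration of the within-set rest block, seconds.
#' @param gesture_s Duration of the gesture block, seconds.
#' @param interround_rest_s Rest between rounds (and gestures), seconds.
#' @param fs Sampling rate in Hz.
#'
#' @return An object of class `emg_schedule`: a list with elements
#'   `blocks` (data frame: `label`, `duration_s`, `start_sample`,
#'   `n_samples`), `round_boundaries` (data frame: `gesture`, `round`,
#'   `start_sample`, `end_sample`), `fs`, `n_samples`, `gestures` and the
#'   call parameters. Sample indices are 1-based and block ranges are
#'   inclusive.
#' @examples
#' sch <- build_schedule(gestures = "rock", rounds = 1, sets_per_round = 1)
#' sch$n_samples  # 20000 = (5 + 5) s at 2000 Hz
#' @export
build_schedule <- function(gestures = emg_gestures(), rounds = 4,
                           sets_per_round = 5, rest_s = 5, gesture_s = 5,
                           interround_rest_s = 10, fs = 2000) {
  if (length(gestures) < 1 || anyNA(gestures) || any(gestures == rest_label()))
    stop("'gestures' must be a non-empty vector of non-rest gesture names")
  if (anyDuplicated(gestures)) stop("'gestures' must be unique")
  if (rounds < 1 || sets_per_round < 1) stop("counts must be >= 1")
  if (rest_s <= 0 || gesture_s <= 0 || interround_rest_s <= 0 || fs <= 0)
    stop("durations and sampling rate must be positive")

  labels <- character(0)
  durs <- numeric(0)
  rb <- list()
  for (g in gestures) {
    for (r in seq_len(rounds)) {
      if (length(labels) > 0) {          # separator before every round but the first
        labels <- c(labels, rest_label())
        durs <- c(durs, interround_rest_s)
      }
      round_start_s <- sum(durs)
      labels <- c(labels, rep(c(rest_label(), g), sets_per_round))
      durs <- c(durs, rep(c(rest_s, gesture_s), sets_per_round))
      rb[[length(rb) + 1]] <- data.frame(
        gesture = g, round = r,
        start_sample = round(round_start_s * fs) + 1L,
        end_sample = round(sum(durs) * fs))
    }
  }
  n_per_block <- round(durs * fs)
  if (any(abs(n_per_block - durs * fs) > 1e-9))
    stop("block durations must correspond to an integer number of samples")
  blocks <- data.frame(
    label = labels,
    duration_s = durs,
    start_sample = cumsum(c(1L, n_per_block[-length(n_per_block)])),
    n_samples = as.integer(n_per_block))
  structure(list(
    blocks = blocks,
    round_boundaries = do.call(rbind, rb),
    fs = fs,
    n_samples = sum(blocks$n_samples),
    gestures = gestures,
    rounds = rounds, sets_per_round = sets_per_round,
    rest_s = rest_s, gesture_s = gesture_s,
    interround_rest_s = interround_rest_s),
    class = "emg_schedule")
}

#' Per-sample commanded label
#'
#' @param schedule An `emg_schedule`.
#' @return Character vector of length `schedule$n_samples` giving the
#'   commanded block label at each sample.
#' @export
command_labels <- function(schedule) {
  stopifnot(inherits(schedule, "emg_schedule"))
  rep(schedule$blocks$label, schedule$blocks$n_samples)
}

#' Per-sample round ownership
#'
#' Maps every sample to a (gesture, round) pair. Samples inside a round span
#' belong to that round; separator rest samples are attributed to the round
#' they follow (the leading separator of the first round of a gesture is
#' attributed to that upcoming round).
#'
#' @param schedule An `emg_schedule`.
#' @return A data frame with columns `gesture` and `round`, one row per
#'   sample.
#' @keywords internal
round_ownership <- function(schedule) {
  rb <- schedule$round_boundaries
  blk <- schedule$blocks
  # block-level ownership: a block belongs to the round span containing it,
  # otherwise (separator) to the previous block's round
  bg <- character(nrow(blk)); br <- integer(nrow(blk))
  blk_end <- blk$start_sample + blk$n_samples - 1L
  for (i in seq_len(nrow(blk))) {
    j <- which(rb$start_sample <= blk$start_sample[i] & rb$end_sample >= blk_end[i])
    if (length(j) == 1L) { bg[i] <- rb$gesture[j]; br[i] <- rb$round[j] }
    else if (i > 1L) { bg[i] <- bg[i - 1L]; br[i] <- br[i - 1L] }
  }
  if (br[1] == 0L) { bg[1] <- rb$gesture[1]; br[1] <- rb$round[1] }
  data.frame(gesture = rep(bg, blk$n_samples), round = rep(br, blk$n_samples))
}

#' @export
print.emg_schedule <- function(x, ...) {
  cat("<emg_schedule>\n")
  cat(sprintf("  %d gesture(s) x %d round(s) x %d set(s); fs = %g Hz\n",
              length(x$gestures), x$rounds, x$sets_per_round, x$fs))
  cat(sprintf("  %d blocks, %d samples (%.1f s)\n", nrow(x$blocks),
              x$n_samples, x$n_samples / x$fs))
  invisible(x)
}
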