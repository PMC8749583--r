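#' Overlapping-window specification
#'
#' Defaults give 250 ms windows advanced in 25 ms steps, i.e. 90 % overlap
#' (500 and 50 samples at 2000 Hz).
#'
#' @param window_s Window length, seconds.
#' @param step_s Step between consecutive window starts, seconds.
#' @return An object of class `emg_windowing`.
#' @export
windowing_spec <- function(window_s = 0.25, step_s = 0.025) {
  if (!(step_s > 0 && step_s <= window_s))
    stop("need 0 < step_s <= window_s")
  structure(list(window_s = window_s, step_s = step_s),
            class = "emg_windowing")
}

#' Fractional overlap of a windowing specification
#' @param spec An `emg_windowing`.
#' @return `(window_s - step_s) / window_s`.
#' @export
window_overlap <- function(spec) (spec$window_s - spec$step_s) / spec$window_s

window_samples <- function(spec, fs) {
  w <- round(spec$window_s * fs)
  s <- round(spec$step_s * fs)
  if (w < 1 || s < 1) stop("window and step must be at least one sample")
  c(window = as.integer(w), step = as.integer(s))
}

#' Window start positions over a signal
#'
#' Enumerates 1-based start samples of all complete windows:
#' `1, 1 + step, 1 + 2 step, ...` while the window fits, giving
#' `floor((L - W) / S) + 1` windows of length `W` at step `S`.
#'
#' @param n_samples Signal length in samples.
#' @param spec An `emg_windowing`.
#' @param fs Sampling rate, Hz.
#' @return Integer vector of start samples; a window covers
#'   `start : (start + W - 1)`.
#' @export
segment_windows <- function(n_samples, spec = windowing_spec(), fs = 2000) {
  ws <- window_samples(spec, fs)
  if (n_samples < ws["window"])
    stop("signal is shorter than one window")
  count <- (n_samples - ws[["window"]]) %/% ws[["step"]] + 1L
  as.integer(1L + (seq_len(count) - 1L) * ws[["step"]])
}
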