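#' Time-domain EMG features
#'
#' The six classical (Hudgins-style) time-domain features computed on a
#' single window `x` of one channel:
#' \describe{
#'   \item{RMS}{`sqrt(mean(x^2))`.}
#'   \item{VAR}{`mean(x^2)`. Bandpassed EMG is treated as zero-mean, so the
#'     variance is the mean square and `VAR = RMS^2` identically.}
#'   \item{MAV}{`mean(abs(x))`.}
#'   \item{SSC}{number of slope sign changes: interior samples where
#'     `(x[i] - x[i-1]) * (x[i] - x[i+1])` exceeds `threshold`. The default
#'     `mode = "strict"` uses a strict inequality so a flat segment scores
#'     zero; `mode = "literal"` uses `>=`, under which a constant signal
#'     counts every interior sample.}
#'   \item{ZC}{number of zero crossings: adjacent pairs with opposite sign
#'     whose amplitude jump is at least `threshold`.}
#'   \item{WL}{waveform length `sum(abs(diff(x)))`.}
#' }
#'
#' @param x Numeric vector (one channel, one window).
#' @param threshold Non-negative amplitude threshold suppressing
#'   noise-induced counts (ZC, SSC only); default 0.
#' @param mode SSC comparison rule, `"strict"` (`>`) or `"literal"` (`>=`).
#' @return A single number (integer-valued for ZC and SSC).
#' @name td_features
NULL

#' @rdname td_features
#' @export
emg_rms <- function(x) {
  if (length(x) < 1) stop("empty input")
  sqrt(mean(x^2))
}

#' @rdname td_features
#' @export
emg_var <- function(x) {
  if (length(x) < 1) stop("empty input")
  mean(x^2)
}

#' @rdname td_features
#' @export
emg_mav <- function(x) {
  if (length(x) < 1) stop("empty input")
  mean(abs(x))
}

#' @rdname td_features
#' @export
emg_wl <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  sum(abs(diff(x)))
}

#' @rdname td_features
#' @export
emg_zc <- function(x, threshold = 0) {
  if (length(x) < 2) stop("need at least 2 samples")
  if (threshold < 0) stop("'threshold' must be >= 0")
  a <- x[-length(x)]; b <- x[-1]
  sum(a * b < 0 & abs(a - b) >= threshold)
}

#' @rdname td_features
#' @export
emg_ssc <- function(x, threshold = 0, mode = c("strict", "literal")) {
  if (length(x) < 3) stop("need at least 3 samples")
  if (threshold < 0) stop("'threshold' must be >= 0")
  mode <- match.arg(mode)
  n <- length(x)
  v <- (x[2:(n - 1)] - x[1:(n - 2)]) * (x[2:(n - 1)] - x[3:n])
  if (mode == "strict") sum(v > threshold) else sum(v >= threshold)
}

#' Canonical feature column names
#'
#' Channel-major ordering: all six features of channel 1, then channel 2,
#' then channel 3 (`ch1_rms, ch1_var, ch1_mav, ch1_ssc, ch1_zc, ch1_wl,
#' ch2_rms, ...`).
#'
#' @param features Feature subset, in canonical order.
#' @return Character vector of column names (`3 * length(features)`).
#' @export
feature_names <- function(features = c("rms", "var", "mav", "ssc", "zc", "wl")) {
  bad <- setdiff(features, c("rms", "var", "mav", "ssc", "zc", "wl"))
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  as.vector(t(outer(paste0("ch", 1:3, "_"), features, paste0)))
}

#' Extract the 18 time-domain features of one window
#'
#' @param window 3 x N numeric matrix (channels in rows, N >= 3).
#' @param zc_threshold,ssc_threshold Amplitude thresholds for ZC and SSC.
#' @param ssc_mode SSC comparison rule, see [emg_ssc()].
#' @return Named numeric vector of length 18 in canonical channel-major
#'   order.
#' @export
extract_features <- function(window, zc_threshold = 0, ssc_threshold = 0,
                             ssc_mode = "strict") {
  if (!is.matrix(window) || nrow(window) != 3)
    stop("'window' must be a 3 x N matrix")
  if (ncol(window) < 3) stop("window must contain at least 3 samples")
  out <- numeric(0)
  for (ch in 1:3) {
    x <- window[ch, ]
    out <- c(out, emg_rms(x), emg_var(x), emg_mav(x),
             emg_ssc(x, ssc_threshold, ssc_mode),
             emg_zc(x, zc_threshold), emg_wl(x))
  }
  names(out) <- feature_names()
  out
}

#' Feature table for a set of labelled windows
#'
#' Computes the 18 features for every window in `windows` (as produced by
#' [annotate_windows()]) against `recording`. Per-channel window sums are
#' evaluated with cumulative sums, so the cost is linear in the recording
#' length rather than in windows x window length; the result is identical
#' to calling [extract_features()] window by window.
#'
#' @param recording Filtered `emg_recording`.
#' @param windows Data frame with at least `start_sample` (plus any id
#'   columns, which are carried through).
#' @param spec `emg_windowing` defining the window length.
#' @param zc_threshold,ssc_threshold,ssc_mode See [extract_features()].
#' @return `windows` with 18 feature columns appended.
#' @export
feature_table <- function(recording, windows, spec = windowing_spec(),
                          zc_threshold = 0, ssc_threshold = 0,
                          ssc_mode = "strict") {
  stopifnot(inherits(recording, "emg_recording"))
  W <- window_samples(spec, recording$fs)[["window"]]
  s <- windows$start_sample
  if (any(s < 1) || any(s + W - 1L > ncol(recording$samples)))
    stop("window out of recording bounds")
  feat <- matrix(NA_real_, nrow(windows), 18,
                 dimnames = list(NULL, feature_names()))
  for (ch in 1:3) {
    x <- recording$samples[ch, ]
    csq <- c(0, cumsum(x^2))
    cab <- c(0, cumsum(abs(x)))
    d <- diff(x)
    cwl <- c(0, 0, cumsum(abs(d)))                      # pairs (i, i+1)
    zc_ev <- x[-length(x)] * x[-1] < 0 & abs(d) >= zc_threshold
    czc <- c(0, 0, cumsum(zc_ev))
    n <- length(x)
    v <- (x[2:(n - 1)] - x[1:(n - 2)]) * (x[2:(n - 1)] - x[3:n])
    ssc_ev <- if (ssc_mode == "strict") v > ssc_threshold else v >= ssc_threshold
    cssc <- c(0, 0, cumsum(ssc_ev))                     # event at centre i (2..n-1)
    ms <- (csq[s + W] - csq[s]) / W
    pre <- paste0("ch", ch, "_")
    feat[, paste0(pre, "rms")] <- sqrt(ms)
    feat[, paste0(pre, "var")] <- ms
    feat[, paste0(pre, "mav")] <- (cab[s + W] - cab[s]) / W
    feat[, paste0(pre, "wl")] <- cwl[s + W] - cwl[s + 1]
    feat[, paste0(pre, "zc")] <- czc[s + W] - czc[s + 1]
    feat[, paste0(pre, "ssc")] <- cssc[s + W - 1] - cssc[s + 1]
  }
  cbind(windows, as.data.frame(feat))
}

#' Fit / apply column standardisation
#'
#' `fit_standardizer()` records the per-column mean and standard deviation
#' of the training features; `apply_standardizer()` maps each column to
#' `(x - mean) / sd`. Constant columns (zero sd) are mapped to zero. The
#' standardiser must always be fitted on training data only and then
#' applied unchanged to validation/test data.
#'
#' @param table Data frame containing the feature columns.
#' @param columns Character vector of columns to standardise; defaults to
#'   every canonical feature column present.
#' @return `fit_standardizer()`: an object of class `emg_standardizer`;
#'   `apply_standardizer()`: `table` with the named columns transformed.
#' @export
fit_standardizer <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(feature_names(), names(table))
  if (length(columns) == 0) stop("no feature columns to standardise")
  if (nrow(table) < 2) stop("need at least 2 rows to fit a standardizer")
  m <- vapply(table[columns], mean, numeric(1))
  s <- vapply(table[columns], stats::sd, numeric(1))
  s[s == 0] <- 1  # constant column: centring alone maps it to zero
  structure(list(columns = columns, mean = m, sd = s),
            class = "emg_standardizer")
}

#' @rdname fit_standardizer
#' @param state An `emg_standardizer`.
#' @export
apply_standardizer <- function(state, table) {
  stopifnot(inherits(state, "emg_standardizer"))
  missing_c <- setdiff(state$columns, names(table))
  if (length(missing_c))
    stop("table lacks fitted column(s): ", paste(missing_c, collapse = ", "))
  for (j in seq_along(state$columns)) {
    cn <- state$columns[j]
    table[[cn]] <- (table[[cn]] - state$mean[j]) / state$sd[j]
  }
  table
}

#' Restrict a feature table to a feature combination
#'
#' Keeps the named features on all three channels (dropping the other
#' feature columns) while preserving id/label columns and the canonical
#' column order.
#'
#' @param table Feature table (data frame).
#' @param combo Non-empty subset of
#'   `c("rms", "var", "mav", "ssc", "zc", "wl")`.
#' @return Reduced data frame with `3 * length(combo)` feature columns.
#' @export
select_combination <- function(table, combo) {
  if (length(combo) == 0) stop("'combo' must contain at least one feature")
  keep <- feature_names(intersect(c("rms", "var", "mav", "ssc", "zc", "wl"),
                                  combo))
  if (length(keep) != 3 * length(unique(combo)))
    stop("unknown feature(s) in 'combo'")
  drop_cols <- setdiff(intersect(feature_names(), names(table)), keep)
  table[, setdiff(names(table), drop_cols), drop = FALSE]
}
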