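#' Specify a Butterworth filter
#'
#' @param kind `"bandpass"` or `"bandstop"`.
#' @param order Filter order of the analog lowpass prototype.
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @return An object of class `emg_filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "bandstop"), order, low_hz, high_hz) {
  kind <- match.arg(kind)
  if (order < 1 || order != round(order)) stop("'order' must be a positive integer")
  if (!(low_hz > 0 && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  structure(list(kind = kind, order = as.integer(order),
                 low_hz = low_hz, high_hz = high_hz),
            class = "emg_filter_spec")
}

#' Default preprocessing filters
#'
#' The two digital filters applied to raw recordings: a 4th-order
#' Butterworth bandpass (20-500 Hz) retaining the band where surface-EMG
#' energy is concentrated, followed by a 7th-order Butterworth bandstop
#' (59.5-60.5 Hz) notching out mains interference.
#'
#' @return List of two `emg_filter_spec` objects, applied in order.
#' @export
default_filter_specs <- function() {
  list(filter_spec("bandpass", 4, 20, 500),
       filter_spec("bandstop", 7, 59.5, 60.5))
}

# Butterworth band filter as zeros/poles/gain in the z-plane.
# The 1 Hz wide notch at a 2000 Hz rate is numerically hopeless in direct
# transfer-function form, so the design stays in zpk and is evaluated as a
# cascade of second-order sections.
butter_zpk <- function(order, low_hz, high_hz, fs, kind) {
  w1 <- 2 * fs * tan(pi * low_hz / fs)   # prewarped analog edges
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit lowpass poles
  if (kind == "bandpass") {
    p1 <- p * bw / 2
    pb <- c(p1 + sqrt(p1^2 - w0^2), p1 - sqrt(p1^2 - w0^2))
    zb <- rep(0 + 0i, order)           # n zeros at s = 0 (plus n at infinity)
    gb <- bw^order
  } else {
    p1 <- (bw / 2) / p
    pb <- c(p1 + sqrt(p1^2 - w0^2), p1 - sqrt(p1^2 - w0^2))
    zb <- rep(c(1i * w0, -1i * w0), order)
    gb <- 1
  }
  fs2 <- 2 * fs
  zd <- (fs2 + zb) / (fs2 - zb)          # bilinear transform
  pd <- (fs2 + pb) / (fs2 - pb)
  kd <- gb * Re(prod(fs2 - zb) / prod(fs2 - pb))
  if (length(zd) < length(pd))           # zeros at analog infinity land at z = -1
    zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  list(z = zd, p = pd, k = kd)
}

poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

zpk_to_sos <- function(z, p, k) {
  pair_up <- function(v) {
    out <- list(); used <- rep(FALSE, length(v))
    for (i in order(-abs(v))) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(v[i])) > 1e-10) {
        j <- which(!used & abs(v - Conj(v[i])) < 1e-8)[1]
        if (is.na(j)) stop("unpaired complex root in filter design")
        used[j] <- TRUE
        out[[length(out) + 1]] <- c(v[i], v[j])
      } else {
        j <- which(!used & abs(Im(v)) <= 1e-10)
        if (length(j)) { j <- j[1]; used[j] <- TRUE; out[[length(out) + 1]] <- c(v[i], v[j]) }
        else out[[length(out) + 1]] <- v[i]
      }
    }
    out
  }
  pp <- pair_up(p); zz <- pair_up(z)
  ns <- max(length(pp), length(zz))
  sos <- matrix(0, ns, 6)
  for (s in seq_len(ns)) {
    ps <- if (s <= length(pp)) pp[[s]] else complex(0)
    zs <- if (s <= length(zz)) zz[[s]] else complex(0)
    a <- Re(poly_from_roots(ps)); b <- Re(poly_from_roots(zs))
    sos[s, ] <- c(c(b, rep(0, 3 - length(b))), c(a, rep(0, 3 - length(a))))
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

butter_sos <- function(spec, fs) {
  if (spec$high_hz >= fs / 2)
    stop("filter edge frequency must be below the Nyquist frequency")
  d <- butter_zpk(spec$order, spec$low_hz, spec$high_hz, fs,
                  if (spec$kind == "bandpass") "bandpass" else "bandstop")
  zpk_to_sos(d$z, d$p, d$k)
}

sos_filter <- function(sos, x) {
  for (s in seq_len(nrow(sos)))
    x <- signal::filter(sos[s, 1:3], sos[s, 4:6], x)
  as.numeric(x)
}

sos_filtfilt <- function(sos, x) {
  rev(sos_filter(sos, rev(sos_filter(sos, x))))
}

#' Filter a single signal vector
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param specs List of `emg_filter_spec`, applied in order.
#' @param zero_phase If `TRUE`, each filter is run forward and backward
#'   (zero phase distortion, non-causal); the default single causal pass
#'   matches a real-time system.
#' @return Filtered numeric vector of the same length.
#' @export
filter_signal <- function(x, fs, specs = default_filter_specs(),
                          zero_phase = FALSE) {
  if (!all(is.finite(x))) stop("input signal contains non-finite values")
  for (sp in specs) {
    stopifnot(inherits(sp, "emg_filter_spec"))
    sos <- butter_sos(sp, fs)
    x <- if (zero_phase) sos_filtfilt(sos, x) else sos_filter(sos, x)
  }
  x
}

#' Apply the preprocessing filters to a recording
#'
#' Runs each filter over every channel of the recording, in the listed
#' order. Shape, sampling rate and schedule are preserved.
#'
#' @param recording An `emg_recording`.
#' @inheritParams filter_signal
#' @return A filtered `emg_recording`.
#' @export
apply_filters <- function(recording, specs = default_filter_specs(),
                          zero_phase = FALSE) {
  stopifnot(inherits(recording, "emg_recording"))
  for (sp in specs)
    if (sp$high_hz >= recording$fs / 2)
      stop("filter edge frequency must be below the Nyquist frequency")
  out <- recording
  for (ch in seq_len(nrow(recording$samples)))
    out$samples[ch, ] <- filter_signal(recording$samples[ch, ], recording$fs,
                                       specs, zero_phase)
  out$filtered <- TRUE
  out
}
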