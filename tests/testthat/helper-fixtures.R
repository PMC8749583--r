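# Shared fixtures, memoised so expensive synthetic recordings are built once
# per test run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# One mid-sized synthetic subject: 9 gestures x 2 rounds x 1 set.
demo_feature_table <- function() {
  memo("demo_tab", function() {
    sch <- build_schedule(rounds = 2, sets_per_round = 1)
    rec <- synthesize_recording(sch, subject_profile(seed = 7))
    process_recording(rec)
  })
}

# A 4-round subject for round-based splitting and large holdout sets.
quad_feature_table <- function() {
  memo("quad_tab", function() {
    sch <- build_schedule(rounds = 4, sets_per_round = 1)
    rec <- synthesize_recording(sch, subject_profile(seed = 11))
    process_recording(rec)
  })
}

# Hand-made recording from an explicit samples matrix (piecewise signals for
# threshold tests).
make_recording <- function(samples, schedule, subject_id = "toy") {
  structure(list(samples = samples, fs = schedule$fs, schedule = schedule,
                 subject_id = subject_id, envelope = NULL, filtered = TRUE),
            class = "emg_recording")
}

# Gaussian-blob feature tables with the canonical 18 feature columns, for
# classifier tests independent of the signal pipeline.
make_blob_ds <- function(n_per_class, k = 10, sep = 5, seed = 1,
                         shuffle_labels = FALSE) {
  set.seed(seed)
  classes <- c(rest_label(), emg_gestures())[seq_len(k)]
  centers <- matrix(rnorm(k * 18), k, 18) * sep
  lab <- rep(classes, each = n_per_class)
  x <- centers[rep(seq_len(k), each = n_per_class), ] +
    matrix(rnorm(k * n_per_class * 18), k * n_per_class, 18)
  colnames(x) <- feature_names()
  if (shuffle_labels) lab <- sample(lab)
  ds <- data.frame(label = lab, round = rep_len(1:4, k * n_per_class))
  cbind(ds, as.data.frame(x))
}

# Brute-force reference implementations of the six time-domain features,
# written as direct formula loops, independent of the package's vectorised
# code paths.
brute_features <- function(x, zc_thr = 0, ssc_thr = 0, ssc_literal = FALSE) {
  n <- length(x)
  rms <- sqrt(sum(x^2) / n)
  va <- sum(x^2) / n
  mav <- sum(abs(x)) / n
  wl <- 0
  for (i in 1:(n - 1)) wl <- wl + abs(x[i + 1] - x[i])
  zc <- 0
  for (i in 1:(n - 1))
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= zc_thr) zc <- zc + 1
  ssc <- 0
  for (i in 2:(n - 1)) {
    v <- (x[i] - x[i - 1]) * (x[i] - x[i + 1])
    if (if (ssc_literal) v >= ssc_thr else v > ssc_thr) ssc <- ssc + 1
  }
  c(rms = rms, var = va, mav = mav, ssc = ssc, zc = zc, wl = wl)
}
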