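test_that("window enumeration matches the closed-form count", {
  expect_equal(segment_windows(500, windowing_spec(0.25, 0.25), 2000), 1L)
  expect_length(segment_windows(10000, windowing_spec(), 2000), 191L)
  expect_error(segment_windows(499, windowing_spec(), 2000), "shorter")

  # property: count and spacing agree with direct enumeration
  set.seed(3)
  for (i in 1:50) {
    W <- sample(10:400, 1)
    S <- sample(seq_len(W), 1)
    L <- W + sample(0:2000, 1)
    starts <- segment_windows(L, windowing_spec(W / 1000, S / 1000), 1000)
    brute <- seq(1L, L - W + 1L, by = S)
    expect_identical(starts, as.integer(brute))
    expect_length(starts, (L - W) %/% S + 1L)
  }
})

test_that("windowing spec reports 90 % overlap at defaults", {
  expect_equal(window_overlap(windowing_spec()), 0.9)
  expect_error(windowing_spec(0.25, 0.3), "step_s <= window_s")
})

piecewise_recording <- function(rest_amp = c(1, 1), gesture_amp = 10,
                                spike = NULL) {
  # gestures="rock", rounds follow rest_amp; 1 set of (5 s rest, 5 s gesture)
  sch <- build_schedule(gestures = "rock", rounds = length(rest_amp),
                        sets_per_round = 1)
  lab <- command_labels(sch)
  own <- emgkit:::round_ownership(sch)
  x <- numeric(sch$n_samples)
  for (r in seq_along(rest_amp))
    x[own$round == r & lab == "rest"] <- rest_amp[r]
  x[lab == "rock"] <- gesture_amp
  if (!is.null(spike)) x[spike$at] <- spike$value
  make_recording(rbind(x, x, x), sch)
}

test_that("baseline maximum equals a direct scan of the baseline span", {
  sch <- build_schedule(gestures = "rock", rounds = 1, sets_per_round = 1)
  set.seed(8)
  x <- rnorm(sch$n_samples)
  rec <- make_recording(rbind(x, 2 * x, 3 * x), sch)
  cal <- compute_baseline_max(rec, baseline_span_s = 4, skip_s = 0.25)
  span <- 501:8000  # skip 0.25 s, then up to 4 s of the leading rest
  expect_equal(unname(cal$baseline_max["rock", 1, ]),
               c(max(abs(x[span])), 2 * max(abs(x[span])),
                 3 * max(abs(x[span]))))
})

test_that("lambda_max is the ratio of largest to smallest round baseline", {
  rec <- piecewise_recording(rest_amp = c(1, 2))
  cal <- compute_baseline_max(rec)
  expect_equal(cal$lambda_max, 2)
  expect_equal(unname(cal$channel_base), rep(2, 3))
})

test_that("an all-zero signal fails calibration", {
  sch <- build_schedule(gestures = "rock", rounds = 1, sets_per_round = 1)
  rec <- make_recording(matrix(0, 3, sch$n_samples), sch)
  expect_error(compute_baseline_max(rec), "positive")
})

test_that("lambda selection picks the smallest false-activation-free value", {
  # clean rest: lambda = 1 suffices (strict > comparison, no crossings)
  rec <- piecewise_recording(rest_amp = c(1, 2))
  cal <- compute_baseline_max(rec)
  expect_equal(select_lambda(cal, rec, grid = c(1, 1.5, 2)), 1)

  # one rest spike at 2.5 x channel base 2: lambda 1 trips, 1.5 clears
  spike_at <- 9000  # 4.5 s into round 1's leading rest, outside the baseline
  rec2 <- piecewise_recording(rest_amp = c(1, 2),
                              spike = list(at = spike_at, value = 2.5))
  cal2 <- compute_baseline_max(rec2)
  expect_equal(unname(cal2$channel_base), rep(2, 3))
  expect_equal(select_lambda(cal2, rec2, grid = c(1, 1.5, 2)), 1.5)

  # spike too large for the whole grid: fall back to lambda_max, warn
  rec3 <- piecewise_recording(rest_amp = c(1, 2),
                              spike = list(at = spike_at, value = 10))
  cal3 <- compute_baseline_max(rec3)
  expect_warning(lam <- select_lambda(cal3, rec3, grid = c(1, 1.5, 2)),
                 "lambda_max")
  expect_equal(lam, cal3$lambda_max)

  expect_error(select_lambda(cal, rec, grid = numeric(0)), "non-empty")
  expect_error(select_lambda(cal, rec, grid = c(0.5, 1)), "lambda_max")
})

test_that("activation uses the earliest crossing across channels", {
  sch <- build_schedule(gestures = "rock", rounds = 1, sets_per_round = 1)
  n <- sch$n_samples
  base <- rep(1, n)
  blk_start <- 10001L  # gesture command boundary
  mk <- function(delay_s) {
    x <- base
    x[(blk_start + round(delay_s * 2000)):n] <- 10
    x
  }
  rec <- make_recording(rbind(mk(0.95), mk(1.00), mk(1.10)), sch)
  cal <- compute_baseline_max(rec)
  tl <- detect_activation(rec, cal, lambda = 1)
  expect_equal(tl$points$activation_sample, blk_start + round(0.95 * 2000))
  expect_equal(tl$points$channel, 1L)
  # activated run lasts 5 s from the activation point, clipped at the end
  run <- which(tl$activated)
  onset <- blk_start + round(0.95 * 2000)
  expect_equal(run[1], onset)
  expect_length(run, min(5 * 2000, n - onset + 1L))
})

test_that("a block with no crossing stays inactive", {
  rec <- piecewise_recording(rest_amp = c(1, 1), gesture_amp = 1)
  cal <- compute_baseline_max(rec)
  tl <- detect_activation(rec, cal, lambda = 1)
  expect_equal(sum(tl$activated), 0L)
  expect_equal(nrow(tl$points), 0L)
})

test_that("a crossing at the command boundary activates [t, t + 5 s)", {
  rec <- piecewise_recording(rest_amp = c(1, 1), gesture_amp = 10)
  cal <- compute_baseline_max(rec)
  tl <- detect_activation(rec, cal, lambda = 1)
  sch <- rec$schedule
  gest_starts <- sch$blocks$start_sample[sch$blocks$label == "rock"]
  expect_equal(tl$points$activation_sample, gest_starts)
  expect_equal(sum(tl$activated), length(gest_starts) * 5 * 2000)
})

test_that("the majority rule annotates windows at the exact boundary", {
  sch <- build_schedule(gestures = "rock", rounds = 1, sets_per_round = 1)
  # activation running from sample A: a window [s, s+499] has
  # (s + 499 - A + 1) activated samples
  A <- 10001L
  tl <- structure(list(activated = c(rep(FALSE, A - 1L),
                                     rep(TRUE, sch$n_samples - A + 1L)),
                       points = NULL, activation_s = 5, lambda = 1),
                  class = "emg_timeline")
  w <- annotate_windows(tl, sch)
  n_act <- pmax(0, pmin(w$start_sample + 499L, sch$n_samples) - A + 1L)
  expect_true(all(w$label[n_act > 250] == "rock"))
  expect_true(all(w$label[n_act <= 250] == "rest"))
  # exactly half activated is NOT "more than 50 %"
  half <- which(n_act == 250)
  expect_true(length(half) > 0 && all(w$label[half] == "rest"))
  # fully inside the activated run
  expect_true(all(w$label[n_act == 500] == "rock"))
})

test_that("annotation is idempotent and lambda acts monotonically", {
  tab <- demo_feature_table()
  tl <- attr(tab, "timeline")
  sch <- build_schedule(rounds = 2, sets_per_round = 1)
  w1 <- annotate_windows(tl, sch)
  w2 <- annotate_windows(tl, sch)
  expect_identical(w1, w2)

  rec <- synthesize_recording(sch, subject_profile(seed = 7))
  f <- apply_filters(rec)
  cal <- attr(tab, "calibration")
  lams <- seq(1, cal$lambda_max, length.out = 5)
  counts <- sapply(lams, function(l)
    sum(detect_activation(f, cal, l)$activated))
  expect_true(all(diff(counts) <= 0))
})
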