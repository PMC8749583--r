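test_that("hand-computed feature values are reproduced", {
  expect_equal(emg_rms(c(1, -1, 1, -1)), 1)
  expect_equal(emg_rms(c(0, 0, 0)), 0)
  expect_equal(emg_rms(c(3, 4)), sqrt(12.5))
  expect_equal(emg_var(c(1, -1, 1, -1)), 1)
  expect_equal(emg_var(c(3, 4)), 12.5)
  expect_equal(emg_mav(c(1, -1, 2, -2)), 1.5)
  expect_equal(emg_mav(rep(-3, 5)), 3)
  expect_equal(emg_wl(c(0, 1, 0, 1)), 3)
  expect_equal(emg_wl(rep(2, 4)), 0)
  expect_equal(emg_wl(c(0, 1, 2, 3)), 3)  # telescoping on a monotone ramp
  expect_equal(emg_zc(c(1, -1, 1), 0), 2)
  expect_equal(emg_zc(c(1, 2, 3), 0), 0)
  n <- 17
  expect_equal(emg_zc(rep(c(1, -1), length.out = n)), n - 1)
  expect_equal(emg_ssc(c(0, 1, 0, 1, 0)), 3)
  expect_equal(emg_ssc(1:10), 0)
  expect_equal(emg_ssc(rep(1, 10)), 0)                      # strict mode
  expect_equal(emg_ssc(rep(1, 10), mode = "literal"), 8)    # N - 2
  expect_error(emg_rms(numeric(0)), "empty")
  expect_error(emg_zc(1), "at least 2")
  expect_error(emg_ssc(c(1, 2)), "at least 3")
})

test_that("all six features match a brute-force oracle on random windows", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(10:80, 1)
    x <- rnorm(n) * 10^runif(1, -2, 2)
    zc_thr <- abs(rnorm(1)) * 0.1
    ssc_thr <- abs(rnorm(1)) * 0.01
    ref <- brute_features(x, zc_thr, ssc_thr)
    expect_identical(emg_zc(x, zc_thr), as.integer(ref["zc"]) + 0L)
    expect_identical(emg_ssc(x, ssc_thr), as.integer(ref["ssc"]) + 0L)
    expect_equal(emg_rms(x), ref[["rms"]], tolerance = 1e-12)
    expect_equal(emg_var(x), ref[["var"]], tolerance = 1e-12)
    expect_equal(emg_mav(x), ref[["mav"]], tolerance = 1e-12)
    expect_equal(emg_wl(x), ref[["wl"]], tolerance = 1e-12)
  }
})

test_that("features scale as expected and VAR is RMS squared", {
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(100)
    c_ <- runif(1, 0.1, 10)
    expect_equal(emg_rms(c_ * x), c_ * emg_rms(x))
    expect_equal(emg_mav(c_ * x), c_ * emg_mav(x))
    expect_equal(emg_wl(c_ * x), c_ * emg_wl(x))
    expect_equal(emg_var(c_ * x), c_^2 * emg_var(x))
    expect_identical(emg_zc(c_ * x, 0), emg_zc(x, 0))
    expect_identical(emg_ssc(c_ * x, 0), emg_ssc(x, 0))
    expect_equal(emg_var(x), emg_rms(x)^2)
  }
})

test_that("extract_features composes the single-feature operations", {
  set.seed(6)
  w <- matrix(rnorm(3 * 500), 3)
  fv <- extract_features(w)
  expect_length(fv, 18)
  expect_named(fv, feature_names())
  for (ch in 1:3) {
    x <- w[ch, ]
    expect_equal(unname(fv[paste0("ch", ch, "_rms")]), emg_rms(x))
    expect_equal(unname(fv[paste0("ch", ch, "_ssc")]), emg_ssc(x))
    expect_equal(unname(fv[paste0("ch", ch, "_zc")]), emg_zc(x))
    expect_equal(unname(fv[paste0("ch", ch, "_wl")]), emg_wl(x))
  }
  # identical channels give identical feature blocks
  w2 <- rbind(w[1, ], w[1, ], w[3, ])
  fv2 <- extract_features(w2)
  expect_equal(unname(fv2[1:6]), unname(fv2[7:12]))
  expect_error(extract_features(matrix(rnorm(8), 2)), "3 x N")
})

test_that("the batch feature table equals the per-window path", {
  tab <- demo_feature_table()
  sch <- build_schedule(rounds = 2, sets_per_round = 1)
  rec <- apply_filters(synthesize_recording(sch, subject_profile(seed = 7)))
  idx <- sample(nrow(tab), 40)
  for (i in idx) {
    win <- rec$samples[, tab$start_sample[i]:(tab$start_sample[i] + 499)]
    fv <- extract_features(win)
    expect_equal(unname(unlist(tab[i, feature_names()])), unname(fv),
                 tolerance = 1e-10)
  }
})

test_that("standardisation yields zero mean and unit variance on its fit set", {
  set.seed(7)
  tab <- as.data.frame(matrix(rnorm(200 * 18, mean = 3, sd = 4), 200))
  names(tab) <- feature_names()
  std <- fit_standardizer(tab)
  z <- apply_standardizer(std, tab)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, var) - 1) < 1e-9))

  # constant column maps to zero
  tab$ch1_rms <- 5
  z2 <- apply_standardizer(fit_standardizer(tab), tab)
  expect_true(all(z2$ch1_rms == 0))

  # affine propagation: shifting the fit set by c moves means to c / sd
  shifted <- tab
  cc <- 2.5
  for (cn in feature_names()) shifted[[cn]] <- shifted[[cn]] + cc
  std3 <- fit_standardizer(tab)
  z3 <- apply_standardizer(std3, shifted)
  expect_equal(unname(colMeans(z3[setdiff(feature_names(), "ch1_rms")])),
               unname(cc / std3$sd[setdiff(feature_names(), "ch1_rms")]),
               tolerance = 1e-9)
  expect_error(fit_standardizer(tab[1, , drop = FALSE]), "at least 2 rows")
})

test_that("feature combinations select channel-major column blocks", {
  tab <- as.data.frame(matrix(rnorm(5 * 18), 5))
  names(tab) <- feature_names()
  tab$label <- "rest"
  base <- select_combination(tab, c("zc", "ssc", "wl"))
  expect_length(setdiff(names(base), "label"), 9)
  expect_true(all(grepl("_(zc|ssc|wl)$", setdiff(names(base), "label"))))
  all6 <- select_combination(tab, c("rms", "var", "mav", "ssc", "zc", "wl"))
  expect_length(setdiff(names(all6), "label"), 18)
  expect_error(select_combination(tab, character(0)), "at least one")
  expect_error(select_combination(tab, c("zc", "mystery")), "unknown")
})
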