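# Fixed heteroscedastic four-group dataset; reference values were computed
# once with independent implementations (scipy.stats.levene for the
# mean-centred Levene test, pingouin.welch_anova and
# pingouin.pairwise_gameshowell) and frozen here.
stats_fixture <- function() {
  set.seed(4242)
  g <- rep(c("a", "b", "c", "d"), times = c(12, 15, 10, 18))
  x <- rnorm(55, mean = rep(c(0, 0.8, 0.5, 2.0), times = c(12, 15, 10, 18)),
             sd = rep(c(1, 1.5, 0.7, 2.5), times = c(12, 15, 10, 18)))
  list(x = x, g = g)
}

test_that("Levene's test agrees with the reference implementation", {
  f <- stats_fixture()
  res <- levene_test(f$x, f$g)
  expect_equal(res$W, 5.6092245879, tolerance = 1e-8)
  expect_equal(res$p, 0.0021111644, tolerance = 1e-6)
  # grossly unequal variances are detected
  set.seed(1)
  v <- c(rnorm(30, sd = 1), rnorm(30, sd = 10))
  expect_lt(levene_test(v, rep(c("a", "b"), each = 30))$p, 0.01)
  expect_error(levene_test(1:3, c("a", "a", "b")), ">= 2")
})

test_that("Welch's ANOVA agrees with the reference implementation", {
  f <- stats_fixture()
  res <- welch_anova(f$x, f$g)
  expect_equal(res$F, 3.757651007784, tolerance = 1e-8)
  expect_equal(res$df1, 3)
  expect_equal(res$df2, 27.840222125071, tolerance = 1e-8)
  expect_equal(res$p, 0.022010585657, tolerance = 1e-8)
})

test_that("identical groups give F = 0, p = 1", {
  v <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(c("a", "b"), each = 5)
  res <- welch_anova(v, g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  lev <- levene_test(v, g)
  expect_equal(lev$W, 0)
  expect_equal(lev$p, 1)
})

test_that("two-group Welch ANOVA is the squared Welch t-test", {
  set.seed(7)
  x <- rnorm(20); y <- rnorm(25, mean = 1, sd = 2)
  res <- welch_anova(c(x, y), rep(c("a", "b"), c(20, 25)))
  tt <- t.test(x, y)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$df2, unname(tt$parameter), tolerance = 1e-10)
})

test_that("Welch reduces to classical ANOVA under equal sample variances", {
  # With exactly equal group variances and sizes, Welch's F differs from the
  # classical F only through its denominator 1 + 2(k-2)/(k^2-1) * k(1-1/k)^2
  # / (n-1), which is O(1/n); verify the exact relation and the convergence.
  set.seed(8)
  k <- 3
  for (n in c(100, 1000)) {
    base <- rnorm(n)
    v <- c(base, base + 1, base + 3)     # shifted copies: identical variances
    g <- rep(c("a", "b", "c"), each = n)
    w <- welch_anova(v, g)
    classical <- stats::oneway.test(v ~ factor(g), var.equal = TRUE)
    denom <- 1 + 2 * (k - 2) / (k^2 - 1) * k * (1 - 1 / k)^2 / (n - 1)
    expect_equal(w$F * denom, unname(classical$statistic), tolerance = 1e-9)
    if (n == 1000)
      expect_lt(abs(w$F / unname(classical$statistic) - 1), 1e-3)
  }
})

test_that("Games-Howell agrees with the reference implementation", {
  f <- stats_fixture()
  gh <- games_howell(f$x, f$g)
  expect_equal(nrow(gh), 6)  # k(k-1)/2
  ref <- data.frame(
    group1 = c("a", "a", "a", "b", "b", "c"),
    group2 = c("b", "c", "d", "c", "d", "d"),
    diff = c(-1.026353653942, -0.551288066893, -2.620263786098,
             0.475065587049, -1.593910132155, -2.068975719204),
    df = c(24.956746789331, 19.867129038471, 23.389515113270,
           22.656231286804, 24.691608214806, 22.886571450791),
    p = c(0.202063057263, 0.664021033893, 0.018553149089,
          0.778241691726, 0.243462826641, 0.079176726543))
  expect_equal(gh$group1, ref$group1)
  expect_equal(gh$group2, ref$group2)
  expect_equal(gh$diff, ref$diff, tolerance = 1e-9)
  expect_equal(gh$df, ref$df, tolerance = 1e-8)
  expect_equal(gh$p, ref$p, tolerance = 1e-3)
})

test_that("Games-Howell behaves at the extremes", {
  set.seed(9)
  a <- rnorm(10); b <- a + rnorm(10, sd = 1e-8)
  gh <- games_howell(c(a, b), rep(c("a", "b"), each = 10))
  expect_gt(gh$p, 0.999)
  w <- c(rnorm(10, 0), rnorm(10, 10))
  gh2 <- games_howell(w, rep(c("a", "b"), each = 10))
  expect_lt(gh2$p, 0.001)
})

test_that("pairwise variance F-tests and BH adjustment are correct", {
  set.seed(10)
  x <- rnorm(20)
  vt <- variance_ftests(c(x, x), rep(c("a", "b"), each = 20))
  expect_equal(vt$ratio, 1)
  expect_equal(vt$p, 1)
  expect_equal(vt$p_adj, vt$p)       # single pair: adjusted = raw

  # BH arithmetic on a known p vector
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  # FDR-adjusted p never below raw p, ordering preserved
  f <- stats_fixture()
  vt2 <- variance_ftests(f$x, f$g)
  expect_true(all(vt2$p_adj >= vt2$p - 1e-15))
  expect_equal(order(vt2$p_adj), order(vt2$p))
  # raw p agrees with var.test directly
  direct <- stats::var.test(f$x[f$g == "a"], f$x[f$g == "b"])
  expect_equal(vt2$p[vt2$group1 == "a" & vt2$group2 == "b"], direct$p.value)
})

test_that("confusion matrices normalise and average row-wise", {
  lv <- c("a", "b")
  cm <- confusion_matrix(c("a", "a", "b", "b"), c("a", "a", "a", "b"), lv)
  expect_equal(unname(as.vector(cm)), c(2, 0, 1, 1))  # truth rows, pred cols
  nm <- normalize_confusion(cm)
  expect_equal(unname(rowSums(nm)), c(1, 1))
  # perfect predictions give the identity after normalisation
  perfect <- normalize_confusion(confusion_matrix(lv, lv, lv))
  expect_equal(unname(as.matrix(perfect)), diag(2))
  # averaging: subjects with row-1 sensitivity 1.0 and 0.5
  cm1 <- confusion_matrix(c("a", "b"), c("a", "b"), lv)
  cm2 <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"), lv)
  avg <- average_confusions(list(cm1 + 0, cm2 + 0))
  expect_equal(avg["b", "b"], 0.75)
  expect_equal(average_confusions(list(cm2, cm2)), normalize_confusion(cm2))
  # a truth class absent from a subject is flagged
  expect_warning(normalize_confusion(confusion_matrix("a", "a", lv)),
                 "zero support")
  # accuracy equals the trace over the total
  pred <- c("a", "a", "b", "b", "a")
  truth <- c("a", "b", "b", "b", "a")
  cm3 <- confusion_matrix(pred, truth, lv)
  expect_equal(sum(diag(cm3)) / sum(cm3), accuracy(pred, truth))
})

test_that("the method-comparison report mirrors the analysis plan", {
  set.seed(11)
  methods <- c("ann", "svm", "rf", "lr")
  means <- c(ann = 0.94, svm = 0.87, rf = 0.83, lr = 0.54)
  sds <- c(ann = 0.01, svm = 0.02, rf = 0.03, lr = 0.08)
  acc <- do.call(rbind, lapply(methods, function(m)
    data.frame(subject = sprintf("s%02d", 1:10), method = m,
               accuracy = rnorm(10, means[m], sds[m]))))
  rep <- run_method_comparison(acc)
  expect_s3_class(rep, "emg_stats_report")
  expect_lt(rep$welch_anova$p, 0.05)
  gh <- rep$games_howell
  ann_pairs <- gh[gh$group1 == "ann" | gh$group2 == "ann", ]
  expect_true(all(ann_pairs$p < 0.05))
  # the highest-mean method wins all its pairwise comparisons
  expect_true(all(gh$diff[gh$group1 == "ann"] > 0))
  expect_equal(nrow(gh), 6)
  expect_equal(nrow(rep$variance_ftests), 6)

  single <- run_method_comparison(acc[acc$method == "ann", ])
  expect_null(single$welch_anova)
  expect_equal(single$descriptives$n, 10)

  path <- withr::local_tempfile(fileext = ".json")
  write_stats_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$welch_anova$F, rep$welch_anova$F, tolerance = 1e-9)
})

test_that("the ablation enumerates the eight feature combinations", {
  combos <- ablation_combos()
  expect_length(combos, 8)
  expect_equal(combos[[1]], c("zc", "ssc", "wl"))
  expect_equal(sort(unname(vapply(combos, length, integer(1)) * 3)),
               c(9, 12, 12, 12, 15, 15, 15, 18))
  expect_equal(combos[[8]], c("zc", "ssc", "wl", "mav", "rms", "var"))
})
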