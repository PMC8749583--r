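#' Confusion matrix and row-normalised sensitivities
#'
#' `confusion_matrix()` tabulates counts with the true label in rows and
#' the predicted label in columns. `normalize_confusion()` divides each
#' row by its total, so the diagonal holds per-class sensitivities; rows
#' with zero support are left as `NA` and flagged.
#'
#' @param pred,truth Label vectors over the same class universe.
#' @param levels Class levels fixing the matrix order; defaults to the
#'   union of observed labels.
#' @return `confusion_matrix()`: integer matrix of counts.
#' @export
confusion_matrix <- function(pred, truth, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(pred),
                                               as.character(truth))))
  table(truth = factor(truth, levels), pred = factor(pred, levels))
}

#' @rdname confusion_matrix
#' @param cm Count confusion matrix.
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  if (any(rs == 0)) warning("row(s) with zero support left as NA: ",
                            paste(rownames(cm)[rs == 0], collapse = ", "))
  out <- sweep(cm, 1, rs, "/")
  out[rs == 0, ] <- NA_real_
  out
}

#' Average row-normalised confusion matrices across subjects
#'
#' Each per-subject count matrix is row-normalised first, then entries are
#' averaged element-wise, so every subject contributes equally regardless
#' of test-set size.
#'
#' @param cms List of count confusion matrices with identical dimnames.
#' @return Matrix of averaged sensitivities.
#' @export
average_confusions <- function(cms) {
  stopifnot(length(cms) >= 1)
  normed <- lapply(cms, normalize_confusion)
  Reduce(`+`, normed) / length(normed)
}

#' Levene's test for homogeneity of variance
#'
#' Classical (mean-centred) Levene statistic by default; `center =
#' "median"` gives the Brown-Forsythe variant. Wraps
#' [car::leveneTest()].
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length.
#' @param center `"mean"` or `"median"`.
#' @return List with `W` (the F-like statistic), `df1`, `df2`, `p`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 values each")
  res <- car::leveneTest(values, groups, center = if (center == "mean") mean
                         else stats::median)
  list(W = res[1, "F value"], df1 = res[1, "Df"], df2 = res[2, "Df"],
       p = res[1, "Pr(>F)"])
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F-ratio with Welch-Satterthwaite denominator degrees of
#' freedom, robust to unequal group variances. Wraps
#' [stats::oneway.test()] with `var.equal = FALSE`.
#'
#' @inheritParams levene_test
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2 || any(table(droplevels(groups)) < 2))
    stop("need >= 2 groups with >= 2 values each")
  res <- stats::oneway.test(values ~ groups, var.equal = FALSE)
  list(F = unname(res$statistic), df1 = unname(res$parameter[1]),
       df2 = unname(res$parameter[2]), p = unname(res$p.value))
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' Pairwise comparisons matched to Welch's ANOVA: for groups i and j the
#' statistic `t = |mi - mj| / sqrt(si^2/ni + sj^2/nj)` is referred to the
#' studentized range distribution with `k` groups and Welch-Satterthwaite
#' degrees of freedom, `p = P(q >= t * sqrt(2))`. No installed package
#' provides this procedure, so it is implemented here directly on top of
#' [stats::ptukey()].
#'
#' @inheritParams levene_test
#' @return Data frame with one row per unordered pair: `group1`, `group2`,
#'   `diff` (mean of `group1` minus mean of `group2`), `se`, `t`, `df`,
#'   `p`.
#' @export
games_howell <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 values each")
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  n <- tapply(values, groups, length)
  pairs <- utils::combn(levels(groups), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    diff = NA_real_, se = NA_real_, t = NA_real_,
                    df = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se2 <- v[a] / n[a] + v[b] / n[b]
    df <- se2^2 / ((v[a] / n[a])^2 / (n[a] - 1) + (v[b] / n[b])^2 / (n[b] - 1))
    tt <- abs(m[a] - m[b]) / sqrt(se2)
    out$diff[i] <- m[a] - m[b]
    out$se[i] <- sqrt(se2)
    out$t[i] <- tt
    out$df[i] <- df
    out$p[i] <- stats::ptukey(tt * sqrt(2), nmeans = k, df = df,
                              lower.tail = FALSE)
  }
  out
}

#' Pairwise variance-ratio F-tests with FDR correction
#'
#' Two-sided F-tests of equality of variances for every pair of groups
#' (via [stats::var.test()]), with Benjamini-Hochberg adjustment across
#' the set of pairs.
#'
#' @inheritParams levene_test
#' @return Data frame with `group1`, `group2`, `ratio` (variance of
#'   `group1` over `group2`), `df1`, `df2`, `p`, `p_adj`.
#' @export
variance_ftests <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 values each")
  pairs <- utils::combn(levels(groups), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    ratio = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                    p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    res <- stats::var.test(values[groups == pairs[1, i]],
                           values[groups == pairs[2, i]])
    out$ratio[i] <- unname(res$statistic)
    out$df1[i] <- unname(res$parameter[1])
    out$df2[i] <- unname(res$parameter[2])
    out$p[i] <- res$p.value
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Statistical comparison of classifier families
#'
#' Assembles the full method-comparison report from a per-(subject,
#' method) accuracy table: descriptive statistics, Levene's test, Welch's
#' ANOVA, Games-Howell post-hoc pairs and pairwise variance F-tests with
#' FDR correction. With a single method only the descriptive block is
#' produced.
#'
#' @param acc Data frame with columns `subject`, `method`, `accuracy`.
#' @return An object of class `emg_stats_report` (a list with elements
#'   `descriptives`, `levene`, `welch_anova`, `games_howell`,
#'   `variance_ftests`).
#' @export
run_method_comparison <- function(acc) {
  stopifnot(all(c("subject", "method", "accuracy") %in% names(acc)))
  desc <- do.call(rbind, lapply(split(acc$accuracy, acc$method), function(v)
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))))
  desc <- cbind(method = rownames(desc), desc)
  rownames(desc) <- NULL
  rep <- list(descriptives = desc, levene = NULL, welch_anova = NULL,
              games_howell = NULL, variance_ftests = NULL)
  if (length(unique(acc$method)) >= 2) {
    rep$levene <- levene_test(acc$accuracy, acc$method)
    rep$welch_anova <- welch_anova(acc$accuracy, acc$method)
    rep$games_howell <- games_howell(acc$accuracy, acc$method)
    rep$variance_ftests <- variance_ftests(acc$accuracy, acc$method)
  }
  structure(rep, class = "emg_stats_report")
}

#' Write a stats report as JSON
#'
#' @param report An `emg_stats_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(report, path) {
  stopifnot(inherits(report, "emg_stats_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  invisible(path)
}

#' The eight ablation feature combinations
#'
#' ZC/SSC/WL as the base set plus every subset of \{MAV, RMS, VAR\}.
#'
#' @return Named list of character vectors of feature names.
#' @export
ablation_combos <- function() {
  base <- c("zc", "ssc", "wl")
  extras <- list(character(0), "mav", "rms", "var", c("mav", "rms"),
                 c("mav", "var"), c("rms", "var"), c("mav", "rms", "var"))
  combos <- lapply(extras, function(e) c(base, e))
  names(combos) <- vapply(extras, function(e)
    paste(c("zc/ssc/wl", e), collapse = "+"), character(1))
  combos
}

#' Feature-combination ablation for the MLP classifier
#'
#' Trains and evaluates the MLP on each feature combination (base set
#' ZC/SSC/WL plus subsets of MAV/RMS/VAR) for every subject dataset,
#' then compares combinations with Welch's ANOVA and Games-Howell tests
#' when at least two subjects are available.
#'
#' @param datasets Named list of balanced labelled feature tables, one per
#'   subject.
#' @param params One-row data frame of MLP hyperparameters.
#' @param recipe `emg_ann_recipe`.
#' @param train_frac Holdout training fraction.
#' @param seed Integer seed.
#' @param combos List of feature combinations (default
#'   [ablation_combos()]).
#' @return List: `table` (data frame `subject`, `combo`, `n_features`,
#'   `accuracy`), `welch_anova`, `games_howell` (NULL with < 2 subjects).
#' @export
run_ablation <- function(datasets, params, recipe = ann_recipe(epochs = 100),
                         train_frac = 0.9, seed = 1L,
                         combos = ablation_combos()) {
  rows <- list()
  for (s in seq_along(datasets)) {
    ds <- datasets[[s]]
    sid <- if (!is.null(names(datasets))) names(datasets)[s] else
      sprintf("s%02d", s)
    split <- split_holdout(ds, train_frac, seed + s)
    for (ci in seq_along(combos)) {
      tr <- select_combination(split$train, combos[[ci]])
      te <- select_combination(split$test, combos[[ci]])
      mod <- train_final(tr, "ann", params, recipe, seed + s)
      rows[[length(rows) + 1]] <- data.frame(
        subject = sid, combo = names(combos)[ci],
        n_features = length(feature_columns(tr)),
        accuracy = accuracy(predict(mod, te), te$label))
    }
  }
  tab <- do.call(rbind, rows)
  res <- list(table = tab, welch_anova = NULL, games_howell = NULL)
  if (length(datasets) >= 2) {
    res$welch_anova <- welch_anova(tab$accuracy, tab$combo)
    res$games_howell <- games_howell(tab$accuracy, tab$combo)
  }
  res
}
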