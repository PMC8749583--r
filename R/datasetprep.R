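#' Under-sample the rest class
#'
#' The acquisition protocol yields roughly nine times more rest windows
#' than windows of any single gesture. This randomly discards rest rows
#' (without replacement) until the rest count equals the median per-gesture
#' count, leaving non-rest rows untouched.
#'
#' @param ds Labelled dataset (data frame with a `label` column).
#' @param seed Integer seed; identical seeds retain identical rows.
#' @return The balanced data frame.
#' @export
undersample_rest <- function(ds, seed = 1L) {
  stopifnot("label" %in% names(ds))
  rest_idx <- which(ds$label == rest_label())
  if (length(rest_idx) == 0) {
    warning("no rest rows present; returning dataset unchanged")
    return(ds)
  }
  target <- round(stats::median(table(ds$label[-rest_idx])))
  if (length(rest_idx) <= target) return(ds)
  set.seed(seed)
  keep <- sort(sample(rest_idx, target))
  ds[sort(c(setdiff(seq_len(nrow(ds)), rest_idx), keep)), , drop = FALSE]
}

#' Stratified holdout split
#'
#' Splits a labelled dataset into training and test portions, sampling
#' `train_frac` of each class into the training set so both portions keep
#' the class proportions.
#'
#' @param ds Labelled dataset (data frame with a `label` column).
#' @param train_frac Fraction of each class assigned to training,
#'   strictly between 0 and 1 (default 0.9).
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (disjoint, exhaustive).
#' @export
split_holdout <- function(ds, train_frac = 0.9, seed = 1L) {
  stopifnot("label" %in% names(ds))
  if (!(train_frac > 0 && train_frac < 1))
    stop("'train_frac' must be strictly between 0 and 1")
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in unique(ds$label)) {
    idx <- which(ds$label == cl)
    n_tr <- round(train_frac * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # both sides non-empty per class
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  list(train = ds[train_idx, , drop = FALSE],
       test = ds[-train_idx, , drop = FALSE])
}

#' Round-based split for pseudo-real-time evaluation
#'
#' Training on rounds 1 to `test_round - 1` and testing on the final round
#' approximates deploying a classifier on data recorded after the training
#' session.
#'
#' @param ds Labelled dataset with a `round` column covering rounds
#'   `1:test_round`.
#' @param test_round Round held out for testing (default 4).
#' @return List with `train` (earlier rounds) and `test` (`test_round`).
#' @export
split_by_round <- function(ds, test_round = 4L) {
  stopifnot(all(c("label", "round") %in% names(ds)))
  present <- sort(unique(ds$round))
  if (!all(seq_len(test_round) %in% present))
    stop("dataset must contain all rounds 1..", test_round)
  list(train = ds[ds$round < test_round, , drop = FALSE],
       test = ds[ds$round == test_round, , drop = FALSE])
}
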