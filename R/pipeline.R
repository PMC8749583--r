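#' Run the signal-to-features pipeline on one recording
#'
#' Filters the recording, calibrates the activation threshold on the
#' per-round rest baselines, selects the threshold coefficient (unless a
#' numeric `lambda` is given), detects activation onsets, segments each
#' round into overlapping windows, labels them with the majority-activation
#' rule and computes the 18 time-domain features.
#'
#' @param recording Raw `emg_recording` with a schedule.
#' @param lambda `"auto"` (select via [select_lambda()]) or a numeric
#'   coefficient >= 1.
#' @param filter_specs Preprocessing filters.
#' @param spec Windowing specification.
#' @param zc_threshold,ssc_threshold Feature thresholds.
#' @param zero_phase Use zero-phase (offline) filtering.
#' @param baseline_span_s Baseline length used for calibration, seconds.
#' @return Labelled feature table (data frame); the selected `lambda`,
#'   the `emg_calibration` and the `emg_timeline` are attached as
#'   attributes `lambda`, `calibration` and `timeline`.
#' @export
process_recording <- function(recording, lambda = "auto",
                              filter_specs = default_filter_specs(),
                              spec = windowing_spec(),
                              zc_threshold = 0, ssc_threshold = 0,
                              zero_phase = FALSE, baseline_span_s = 4) {
  stopifnot(inherits(recording, "emg_recording"))
  filtered <- apply_filters(recording, filter_specs, zero_phase)
  calib <- compute_baseline_max(filtered, baseline_span_s)
  lam <- if (identical(lambda, "auto")) select_lambda(calib, filtered)
         else as.numeric(lambda)
  timeline <- detect_activation(filtered, calib, lam)
  windows <- annotate_windows(timeline, recording$schedule, spec,
                              subject_id = recording$subject_id)
  tab <- feature_table(filtered, windows, spec, zc_threshold, ssc_threshold)
  attr(tab, "lambda") <- lam
  attr(tab, "calibration") <- calib
  attr(tab, "timeline") <- timeline
  tab
}

#' Train and evaluate the four classifier families on one subject
#'
#' Balances the rest class, splits the dataset (stratified holdout or
#' round-based), grid-searches each requested method with stratified
#' k-fold cross-validation, refits the winner on the full training set and
#' reports test accuracy and the confusion matrix.
#'
#' @param ds Labelled feature table for one subject.
#' @param methods Subset of `c("ann", "svm", "rf", "lr")`.
#' @param split `"holdout"` (stratified 90/10 by default) or `"rounds"`
#'   (train rounds 1-3, test round 4).
#' @param grid_profile `"full"` or `"fast"` (see [model_grid()]).
#' @param folds CV folds.
#' @param recipe `emg_ann_recipe` for the MLP.
#' @param train_frac Training fraction for the holdout split.
#' @param test_round Held-out round for the round-based split.
#' @param undersample Balance the rest class before splitting.
#' @param seed Integer seed driving every random step.
#' @return List: `accuracies` (data frame `method`, `accuracy`), `models`
#'   (named list of `emg_model`), `confusions` (named list of count
#'   matrices), `splits` (the train/test row counts).
#' @export
evaluate_subject <- function(ds, methods = c("ann", "svm", "rf", "lr"),
                             split = c("holdout", "rounds"),
                             grid_profile = "fast", folds = 10,
                             recipe = ann_recipe(epochs = 100),
                             train_frac = 0.9, test_round = 4L,
                             undersample = TRUE, seed = 1L) {
  split <- match.arg(split)
  if (undersample) ds <- undersample_rest(ds, seed)
  parts <- if (split == "holdout") split_holdout(ds, train_frac, seed)
           else split_by_round(ds, test_round)
  models <- list(); confs <- list(); accs <- numeric(0)
  for (m in methods) {
    gs <- cv_grid_search(parts$train, m, model_grid(m, grid_profile),
                         folds = folds, recipe = recipe, seed = seed)
    mod <- train_final(parts$train, m, gs$best_params, recipe, seed,
                       fold_accuracies = gs$fold_accuracies)
    pred <- predict(mod, parts$test)
    models[[m]] <- mod
    confs[[m]] <- confusion_matrix(pred, parts$test$label,
                                   levels = sort(unique(ds$label)))
    accs[m] <- accuracy(pred, parts$test$label)
  }
  list(accuracies = data.frame(method = methods,
                               accuracy = unname(accs[methods])),
       models = models, confusions = confs,
       splits = c(train = nrow(parts$train), test = nrow(parts$test)))
}
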