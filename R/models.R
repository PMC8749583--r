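#' Training recipe for the MLP classifier
#'
#' Defaults mirror a production training budget (Adam, batch 1024,
#' learning rate 0.001, 2000 epochs). Interactive and test use typically
#' scales `epochs` down.
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate Adam step size.
#' @return An object of class `emg_ann_recipe`.
#' @export
ann_recipe <- function(epochs = 2000, batch_size = 1024,
                       learning_rate = 0.001) {
  if (epochs < 1 || batch_size < 1) stop("'epochs' and 'batch_size' must be >= 1")
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate),
            class = "emg_ann_recipe")
}

#' Hyperparameter grid for one classifier family
#'
#' `profile = "full"` reproduces the complete search spaces: ANN layers
#' \{2,3,4\} x neurons \{300,600,1000\} x dropout \{0.2,0.3\} x batch
#' normalisation \{on,off\}; SVM kernel \{linear,rbf\} x C
#' \{1,10,100,1000\} x gamma \{1,...,1e-4\}; RF trees \{100,500,1000\} x
#' class weight \{balanced_subsample,none\}; LR penalty
#' \{l1,l2,elasticnet,none\} x C \{1,...,1e-4\} x class weight
#' \{balanced,none\} x solver \{lbfgs,saga\}. `profile = "fast"` is a
#' small subset for testing and desk-scale runs.
#'
#' LR grid cells with an incompatible penalty/solver pairing (lbfgs
#' supports only l2/none; elasticnet and l1 require saga) are dropped at
#' construction, mirroring the standard behaviour of sklearn-style
#' solvers.
#'
#' @param method One of `"ann"`, `"svm"`, `"rf"`, `"lr"`.
#' @param profile `"full"` or `"fast"`.
#' @return Data frame, one row per grid point.
#' @export
model_grid <- function(method = c("ann", "svm", "rf", "lr"),
                       profile = c("full", "fast")) {
  method <- match.arg(method)
  profile <- match.arg(profile)
  g <- switch(method,
    ann = if (profile == "full")
      expand.grid(hidden_layers = c(2, 3, 4), neurons = c(300, 600, 1000),
                  dropout = c(0.2, 0.3), batchnorm = c(TRUE, FALSE))
    else
      expand.grid(hidden_layers = 2, neurons = 64,
                  dropout = 0.2, batchnorm = TRUE),
    svm = if (profile == "full")
      expand.grid(kernel = c("linear", "radial"), C = c(1, 10, 100, 1000),
                  gamma = c(1, 0.1, 0.01, 0.001, 0.0001),
                  stringsAsFactors = FALSE)
    else
      expand.grid(kernel = "radial", C = c(10, 100), gamma = 1,
                  stringsAsFactors = FALSE),
    rf = if (profile == "full")
      expand.grid(num_trees = c(100, 500, 1000),
                  class_weight = c("balanced_subsample", "none"),
                  stringsAsFactors = FALSE)
    else
      expand.grid(num_trees = c(100, 300), class_weight = "none",
                  stringsAsFactors = FALSE),
    lr = {
      full <- expand.grid(penalty = c("l1", "l2", "elasticnet", "none"),
                          C = c(1, 0.1, 0.01, 0.001, 0.0001),
                          class_weight = c("balanced", "none"),
                          solver = c("lbfgs", "saga"),
                          stringsAsFactors = FALSE)
      ok <- (full$solver == "saga") |
        (full$solver == "lbfgs" & full$penalty %in% c("l2", "none"))
      full <- full[ok, , drop = FALSE]
      if (profile == "fast")
        full <- full[full$penalty %in% c("l2", "none") & full$C == 1 &
                       full$class_weight == "none" & full$solver == "lbfgs", ,
                     drop = FALSE]
      rownames(full) <- NULL
      full
    })
  g
}

feature_columns <- function(ds) {
  intersect(feature_names(), names(ds))
}

#' Stratified fold assignment
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per observation; each class is spread as
#'   evenly as possible over the folds and every observation lands in
#'   exactly one fold.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class '", cl, "' has fewer than ", k, " observations")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

fit_one <- function(method, params, x, y, recipe, seed) {
  y <- droplevels(as.factor(y))
  switch(method,
    ann = fit_mlp(x, y, hidden_layers = params$hidden_layers,
                  neurons = params$neurons, dropout = params$dropout,
                  batchnorm = params$batchnorm, epochs = recipe$epochs,
                  batch_size = recipe$batch_size,
                  learning_rate = recipe$learning_rate, seed = seed),
    svm = e1071::svm(x, y, kernel = params$kernel, cost = params$C,
                     gamma = params$gamma, scale = FALSE),
    rf = {
      cw <- if (params$class_weight == "balanced_subsample") {
        tab <- table(y)
        w <- as.numeric(sum(tab) / (length(tab) * tab))
        names(w) <- names(tab)
        w
      } else NULL
      ranger::ranger(x = x, y = y, num.trees = params$num_trees,
                     class.weights = cw, seed = seed,
                     num.threads = 1)
    },
    lr = {
      if (params$penalty %in% c("l1", "elasticnet") && params$solver == "lbfgs")
        stop("penalty '", params$penalty, "' is incompatible with solver 'lbfgs'")
      w <- if (params$class_weight == "balanced") {
        tab <- table(y)
        as.numeric((sum(tab) / (length(tab) * tab))[y])
      } else rep(1, length(y))
      if (params$penalty == "none") {
        df <- as.data.frame(x)
        df$.label <- y
        nnet::multinom(.label ~ ., data = df, weights = w, trace = FALSE,
                       maxit = 200, MaxNWts = 100000)
      } else {
        alpha <- switch(params$penalty, l1 = 1, l2 = 0, elasticnet = 0.5)
        lam <- 1 / (params$C * nrow(x))
        # decreasing path: warm starts make a small target lambda reachable
        # where a cold single-lambda fit stalls; thresh loosened to a level
        # that does not affect class predictions
        glmnet::glmnet(x, y, family = "multinomial", alpha = alpha,
                       lambda = lam * 10^seq(4, 0, length.out = 12),
                       weights = w, standardize = FALSE,
                       thresh = 1e-5, maxit = 300000)
      }
    },
    stop("unknown method: ", method))
}

predict_one <- function(method, fit, x, classes) {
  pred <- switch(method,
    ann = as.character(predict(fit, x)),
    svm = as.character(predict(fit, x)),
    rf = as.character(predict(fit, data = x)$predictions),
    lr = if (inherits(fit, "multinom"))
      as.character(predict(fit, newdata = as.data.frame(x), type = "class"))
    else as.character(predict(fit, newx = x, type = "class",
                              s = min(fit$lambda))[, 1]))
  factor(pred, levels = classes)
}

#' Classification accuracy
#' @param pred,truth Vectors of equal length.
#' @return Fraction of exact matches, in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  mean(as.character(pred) == as.character(truth))
}

#' Grid search with stratified k-fold cross-validation
#'
#' For each grid point, fits the model on nine of ten stratified folds and
#' scores validation accuracy on the held-out fold, rotating folds so every
#' row is validated exactly once; the point with the highest mean fold
#' accuracy wins (ties broken by grid order, first wins). The feature
#' standardiser is refitted inside every fold on the fold-training rows
#' only, so no validation information leaks into the transform.
#'
#' @param ds Labelled dataset (data frame with `label` and feature
#'   columns).
#' @param method `"ann"`, `"svm"`, `"rf"` or `"lr"`.
#' @param grid Data frame of hyperparameter candidates
#'   (see [model_grid()]).
#' @param folds Number of CV folds (default 10).
#' @param recipe `emg_ann_recipe` used when `method = "ann"`.
#' @param seed Integer seed (fold assignment and model fitting).
#' @return List: `best_params` (one-row data frame), `fold_accuracies`
#'   (the winning point's per-fold accuracies), `results` (mean CV
#'   accuracy per grid point).
#' @export
cv_grid_search <- function(ds, method, grid = model_grid(method, "fast"),
                           folds = 10, recipe = ann_recipe(epochs = 100),
                           seed = 1L) {
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  fcols <- feature_columns(ds)
  labels <- as.factor(ds$label)
  classes <- levels(labels)
  fold <- stratified_folds(labels, folds, seed)
  acc <- matrix(NA_real_, nrow(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    std <- fit_standardizer(ds[tr, , drop = FALSE], fcols)
    x_tr <- as.matrix(apply_standardizer(std, ds[tr, , drop = FALSE])[fcols])
    x_va <- as.matrix(apply_standardizer(std, ds[!tr, , drop = FALSE])[fcols])
    y_tr <- labels[tr]
    y_va <- labels[!tr]
    for (gi in seq_len(nrow(grid))) {
      fit <- fit_one(method, grid[gi, , drop = FALSE], x_tr, y_tr, recipe,
                     seed + gi)
      acc[gi, f] <- accuracy(predict_one(method, fit, x_va, classes), y_va)
    }
  }
  mean_acc <- rowMeans(acc)
  best <- which.max(mean_acc)  # first maximum wins
  list(best_params = grid[best, , drop = FALSE],
       fold_accuracies = acc[best, ],
       results = cbind(grid, mean_cv_accuracy = mean_acc))
}

#' Fit the final model on the full training set
#'
#' Fits the feature standardiser on the whole training set, then the
#' classifier on the standardised features with the chosen
#' hyperparameters.
#'
#' @inheritParams cv_grid_search
#' @param params One-row data frame of hyperparameters (e.g.
#'   `best_params` from [cv_grid_search()]).
#' @param fold_accuracies Optional CV fold accuracies stored with the
#'   model.
#' @return An object of class `emg_model`.
#' @export
train_final <- function(ds, method, params, recipe = ann_recipe(epochs = 100),
                        seed = 1L, fold_accuracies = NULL) {
  fcols <- feature_columns(ds)
  labels <- droplevels(as.factor(ds$label))
  std <- fit_standardizer(ds, fcols)
  x <- as.matrix(apply_standardizer(std, ds)[fcols])
  fit <- fit_one(method, params, x, labels, recipe, seed)
  structure(list(method = method, params = params, standardizer = std,
                 fit = fit, classes = levels(labels),
                 fold_accuracies = fold_accuracies),
            class = "emg_model")
}

#' Predict gesture labels with a trained model
#'
#' @param object An `emg_model`.
#' @param newdata Data frame containing the feature columns used in
#'   training.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.emg_model <- function(object, newdata, ...) {
  x <- as.matrix(apply_standardizer(object$standardizer,
                                    newdata)[object$standardizer$columns])
  predict_one(object$method, object$fit, x, object$classes)
}

#' @export
print.emg_model <- function(x, ...) {
  cat(sprintf("<emg_model> %s (%d classes)\n", toupper(x$method),
              length(x$classes)))
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  if (!is.null(x$fold_accuracies))
    cat(sprintf("  CV accuracy: %.3f (mean of %d folds)\n",
                mean(x$fold_accuracies), length(x$fold_accuracies)))
  invisible(x)
}
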