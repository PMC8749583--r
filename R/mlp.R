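#' Multilayer perceptron for tabular features
#'
#' A fully connected softmax classifier trained with Adam on categorical
#' cross-entropy. Every hidden layer is linear -> (optional) batch
#' normalisation -> ReLU -> (optional) dropout, all layers having the same
#' width. Weights use He-normal initialisation. Batch normalisation keeps
#' exponential running statistics (momentum 0.9) for inference; dropout is
#' inverted so inference needs no rescaling.
#'
#' This is the network used as the "ANN" classifier family; the defaults of
#' the training recipe live in [ann_recipe()].
#'
#' @param x Numeric matrix (rows = observations, columns = features),
#'   already standardised.
#' @param y Factor of class labels.
#' @param hidden_layers Number of hidden layers.
#' @param neurons Width of each hidden layer.
#' @param dropout Dropout probability in `[0, 1)`.
#' @param batchnorm Logical, apply batch normalisation in hidden layers.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed (initialisation and batch shuffling).
#' @return An object of class `emg_mlp`.
#' @export
fit_mlp <- function(x, y, hidden_layers = 2, neurons = 64, dropout = 0.2,
                    batchnorm = TRUE, epochs = 100, batch_size = 1024,
                    learning_rate = 0.001, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (epochs < 1 || batch_size < 1) stop("'epochs' and 'batch_size' must be >= 1")
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  K <- length(classes)
  n <- nrow(x)
  yi <- as.integer(y)
  set.seed(seed)
  eps <- 1e-5

  dims <- c(ncol(x), rep(neurons, hidden_layers), K)
  L <- length(dims) - 1L          # trainable layers (last one is softmax head)
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- dims[l]
    W <- matrix(stats::rnorm(fan_in * dims[l + 1], sd = sqrt(2 / fan_in)),
                fan_in, dims[l + 1])
    bn <- batchnorm && l < L
    layers[[l]] <- list(
      W = W, b = numeric(dims[l + 1]), bn = bn,
      gamma = if (bn) rep(1, dims[l + 1]), beta = if (bn) numeric(dims[l + 1]),
      run_mean = if (bn) numeric(dims[l + 1]), run_var = if (bn) rep(1, dims[l + 1]))
  }

  # Adam state, one slot per parameter array
  adam <- lapply(layers, function(ly) {
    zero <- function(p) if (is.null(p)) NULL else p * 0
    list(mW = zero(ly$W), vW = zero(ly$W), mb = zero(ly$b), vb = zero(ly$b),
         mg = zero(ly$gamma), vg = zero(ly$gamma),
         mB = zero(ly$beta), vB = zero(ly$beta))
  })
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8; step <- 0L

  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    batch_starts <- seq(1, n, by = batch_size)
    for (bs in batch_starts) {
      idx <- perm[bs:min(n, bs + batch_size - 1L)]
      m_b <- length(idx)
      A <- x[idx, , drop = FALSE]
      cache <- vector("list", L)
      # ---- forward ----
      for (l in seq_len(L)) {
        ly <- layers[[l]]
        Z <- A %*% ly$W
        if (!ly$bn) Z <- sweep(Z, 2, ly$b, "+")
        c_l <- list(A_in = A)
        if (ly$bn) {
          mu <- colMeans(Z)
          va <- colMeans(Z^2) - mu^2
          xhat <- sweep(sweep(Z, 2, mu, "-"), 2, sqrt(va + eps), "/")
          Z <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
          layers[[l]]$run_mean <- 0.9 * ly$run_mean + 0.1 * mu
          layers[[l]]$run_var <- 0.9 * ly$run_var + 0.1 * va
          c_l$xhat <- xhat; c_l$inv_sd <- 1 / sqrt(va + eps)
        }
        if (l < L) {
          c_l$relu <- Z > 0
          A <- Z * c_l$relu
          if (dropout > 0) {
            mask <- matrix(stats::runif(length(A)) >= dropout,
                           nrow(A), ncol(A)) / (1 - dropout)
            A <- A * mask
            c_l$drop <- mask
          }
        } else {
          Zs <- Z - apply(Z, 1, max)
          P <- exp(Zs) / rowSums(exp(Zs))
          c_l$P <- P
        }
        cache[[l]] <- c_l
      }
      # ---- backward ----
      step <- step + 1L
      G <- cache[[L]]$P
      G[cbind(seq_len(m_b), yi[idx])] <- G[cbind(seq_len(m_b), yi[idx])] - 1
      dA <- G / m_b
      for (l in rev(seq_len(L))) {
        ly <- layers[[l]]
        c_l <- cache[[l]]
        dZ <- dA
        if (l < L) {
          if (dropout > 0) dZ <- dZ * c_l$drop
          dZ <- dZ * c_l$relu
        }
        grads <- list()
        if (ly$bn) {
          dgamma <- colSums(dZ * c_l$xhat)
          dbeta <- colSums(dZ)
          m_rows <- nrow(dZ)
          dxhat <- sweep(dZ, 2, ly$gamma, "*")
          dZ <- sweep(dxhat -
                        matrix(colMeans(dxhat), m_rows, ncol(dxhat), byrow = TRUE) -
                        c_l$xhat * matrix(colMeans(dxhat * c_l$xhat),
                                          m_rows, ncol(dxhat), byrow = TRUE),
                      2, c_l$inv_sd, "*")
          grads$gamma <- dgamma; grads$beta <- dbeta
        } else {
          grads$b <- colSums(dZ)
        }
        grads$W <- crossprod(c_l$A_in, dZ)
        if (l > 1) dA <- dZ %*% t(ly$W)
        # Adam step for this layer
        upd <- function(par, g, mname, vname) {
          st <- adam[[l]]
          m1 <- beta1 * st[[mname]] + (1 - beta1) * g
          v1 <- beta2 * st[[vname]] + (1 - beta2) * g^2
          adam[[l]][[mname]] <<- m1
          adam[[l]][[vname]] <<- v1
          mhat <- m1 / (1 - beta1^step)
          vhat <- v1 / (1 - beta2^step)
          par - learning_rate * mhat / (sqrt(vhat) + aeps)
        }
        layers[[l]]$W <- upd(ly$W, grads$W, "mW", "vW")
        if (ly$bn) {
          layers[[l]]$gamma <- upd(ly$gamma, grads$gamma, "mg", "vg")
          layers[[l]]$beta <- upd(ly$beta, grads$beta, "mB", "vB")
        } else {
          layers[[l]]$b <- upd(ly$b, grads$b, "mb", "vb")
        }
      }
    }
  }
  structure(list(layers = layers, classes = classes, dropout = dropout,
                 batchnorm = batchnorm, eps = eps,
                 hidden_layers = hidden_layers, neurons = neurons),
            class = "emg_mlp")
}

#' Predict classes or probabilities from a fitted MLP
#'
#' @param object An `emg_mlp`.
#' @param x Numeric matrix with the training feature layout.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or a matrix of class
#'   probabilities.
#' @export
predict.emg_mlp <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  A <- as.matrix(x)
  L <- length(object$layers)
  for (l in seq_len(L)) {
    ly <- object$layers[[l]]
    Z <- A %*% ly$W
    if (!ly$bn) Z <- sweep(Z, 2, ly$b, "+")
    if (ly$bn) {
      Z <- sweep(sweep(Z, 2, ly$run_mean, "-"), 2,
                 sqrt(ly$run_var + object$eps), "/")
      Z <- sweep(sweep(Z, 2, ly$gamma, "*"), 2, ly$beta, "+")
    }
    A <- if (l < L) pmax(Z, 0) else Z
  }
  Zs <- A - apply(A, 1, max)
  P <- exp(Zs) / rowSums(exp(Zs))
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}
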