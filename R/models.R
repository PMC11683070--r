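# The seven estimation model families with fixed hyperparameters.
#
# The tree learners (random forest, gradient boosting) are backed by the
# compiled exact-greedy tree builder in src/trees.cpp; the kernel, latent
# variable and neural models are implemented directly on base linear
# algebra.  Hyperparameters are frozen at construction: PLS uses 2
# components; SVR an RBF kernel with C = 1, epsilon = 0.2; RF 30 trees of
# depth 5; XGB 30 trees of depth 4, learning rate 0.1, L1 = L2 = 0.5; the
# neural network one hidden layer of 100 ReLU units, Adam with adaptive
# learning rate, at most 500 epochs.

.model_families <- c("LR", "QCR", "PLS", "SVR", "RF", "XGB", "NN")

.default_hyper <- list(
  LR  = list(),
  QCR = list(),
  PLS = list(n_components = 2L),
  SVR = list(kernel = "rbf", C = 1.0, epsilon = 0.2, gamma = "scale",
             max_passes = 200L, tol = 1e-4),
  RF  = list(n_estimators = 30L, max_depth = 5L),
  XGB = list(n_estimators = 30L, max_depth = 4L, learning_rate = 0.1,
             reg_alpha = 0.5, reg_lambda = 0.5),
  NN  = list(hidden = 100L, max_iter = 500L, activation = "relu",
             learning_rate = "adaptive", lr_init = 1e-3, alpha = 1e-4,
             batch_size = 200L, tol = 1e-4)
)

#' Model configuration
#'
#' A model family with its fixed hyperparameters.  Hyperparameters are
#' frozen defaults per family and cannot be altered after construction
#' (the benchmark compares families, not tunings); `seed` controls every
#' internal source of randomness (bootstrap resampling, weight
#' initialisation, minibatch shuffling).
#'
#' @param family one of `"LR"`, `"QCR"`, `"PLS"`, `"SVR"`, `"RF"`,
#'   `"XGB"`, `"NN"`.  LR and QCR accept exactly one input column.
#' @param seed integer seed.
#' @return a `model_config` object.
#' @export
model_config <- function(family, seed = 1L) {
  family <- match.arg(family, .model_families)
  structure(list(family = family, hyper = .default_hyper[[family]],
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Fit a configured model
#'
#' @param config a [model_config()].
#' @param x feature matrix/data.frame (single column for LR/QCR).
#' @param y numeric target.
#' @return fitted model object (class `nsat_model`); use
#'   [predict.nsat_model()].
#' @export
fit_model <- function(config, x, y) {
  stopifnot(inherits(config, "model_config"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x/y length mismatch", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("validation error: non-finite features or target", call. = FALSE)
  fitter <- switch(config$family,
                   LR = .fit_lr, QCR = .fit_qcr, PLS = .fit_pls,
                   SVR = .fit_svr, RF = .fit_rf, XGB = .fit_xgb,
                   NN = .fit_nn)
  fit <- fitter(x, y, config$hyper, config$seed)
  fit$family <- config$family
  fit$config <- config
  fit$feature_names <- colnames(x)
  class(fit) <- c(paste0("nsat_", tolower(config$family)), "nsat_model")
  fit
}

#' Predict from a fitted model
#'
#' @param object fitted model from [fit_model()].
#' @param newdata feature matrix/data.frame with the training columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.nsat_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  switch(object$family,
         LR  = drop(cbind(1, x) %*% object$coef),
         QCR = drop(cbind(1, x, x^2) %*% object$coef),
         PLS = drop(scale(x, object$center, object$scale) %*% object$beta) +
               object$intercept,
         SVR = .predict_svr(object, x),
         RF  = .predict_forest(object, x),
         XGB = .predict_forest(object, x),
         NN  = .predict_nn(object, x))
}

# ---- simple regressions ----------------------------------------------------

.fit_lr <- function(x, y, hyper, seed) {
  if (ncol(x) != 1L)
    stop("LR accepts exactly one input column", call. = FALSE)
  if (stats::var(x[, 1]) == 0)
    stop("fit error: constant predictor", call. = FALSE)
  list(coef = stats::lm.fit(cbind(1, x), y)$coefficients)
}

.fit_qcr <- function(x, y, hyper, seed) {
  if (ncol(x) != 1L)
    stop("QCR accepts exactly one input column", call. = FALSE)
  if (stats::var(x[, 1]) == 0)
    stop("fit error: constant predictor", call. = FALSE)
  list(coef = stats::lm.fit(cbind(1, x, x^2), y)$coefficients)
}

#' Simple one-variable regression (linear or quadratic)
#'
#' Least-squares fit of `y = b0 + b1 x` (LR) or
#' `y = b0 + b1 x + b2 x^2` (QCR) on a single mean-index column, with
#' in-sample evaluation metrics, mirroring exploratory per-channel
#' regressions.
#'
#' @param x single predictor vector (e.g. a channel mean).
#' @param y target vector.
#' @param family `"LR"` or `"QCR"`.
#' @return list with `coefficients`, `fitted`, and in-sample `metrics`.
#' @export
fit_simple_regression <- function(x, y, family = c("LR", "QCR")) {
  family <- match.arg(family)
  m <- fit_model(model_config(family), matrix(as.numeric(x), ncol = 1), y)
  fitted <- predict(m, matrix(as.numeric(x), ncol = 1))
  list(coefficients = unname(m$coef), fitted = fitted,
       metrics = evaluation_metrics(y, fitted), model = m)
}

# ---- standardisation helper ------------------------------------------------

.standardise <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(x = scale(x, ctr, scl), center = ctr, scale = scl)
}

# ---- partial least squares (NIPALS, univariate response) -------------------

.fit_pls <- function(x, y, hyper, seed) {
  st <- .standardise(x)
  X <- st$x
  ybar <- mean(y)
  y0 <- y - ybar
  k <- min(hyper$n_components, ncol(x), nrow(x) - 1L)
  p <- ncol(X)
  W <- matrix(0, p, k); P <- matrix(0, p, k); Q <- numeric(k)
  Xd <- X
  for (j in seq_len(k)) {
    w <- drop(crossprod(Xd, y0))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { k <- j - 1L; break }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    pj <- drop(crossprod(Xd, t)) / tt
    qj <- sum(y0 * t) / tt
    Xd <- Xd - tcrossprod(t, pj)
    y0 <- y0 - qj * t
    W[, j] <- w; P[, j] <- pj; Q[j] <- qj
  }
  if (k == 0L) {
    beta <- rep(0, p)
  } else {
    W <- W[, seq_len(k), drop = FALSE]
    P <- P[, seq_len(k), drop = FALSE]
    beta <- drop(W %*% solve(crossprod(P, W), Q[seq_len(k)]))
  }
  list(beta = beta, intercept = ybar, center = st$center, scale = st$scale,
       n_components = k)
}

# ---- support vector regression ---------------------------------------------

# Epsilon-insensitive SVR with RBF kernel, solved by cyclic coordinate
# descent on the dual coefficients beta = alpha - alpha*.  The intercept
# is absorbed into the kernel (K + 1), i.e. it is regularised like the
# other coefficients; this removes the equality constraint so every
# coordinate update has the closed form
#   beta_i <- clip( S(y_i - r_i, epsilon) / K_ii, -C, C )
# with S the soft-threshold operator and r_i the fitted value excluding
# coordinate i.  Deterministic (fixed sweep order).

.rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

.fit_svr <- function(x, y, hyper, seed) {
  st <- .standardise(x)
  X <- st$x
  n <- nrow(X)
  gamma <- if (identical(hyper$gamma, "scale"))
    1 / (ncol(X) * stats::var(as.vector(X))) else hyper$gamma
  K <- .rbf_kernel(X, X, gamma) + 1
  C <- hyper$C; eps <- hyper$epsilon
  beta <- numeric(n)
  r <- numeric(n)                       # r = K beta
  kd <- diag(K)
  for (pass in seq_len(hyper$max_passes)) {
    delta_max <- 0
    for (i in seq_len(n)) {
      u <- y[i] - (r[i] - kd[i] * beta[i])
      bi <- sign(u) * max(abs(u) - eps, 0) / kd[i]
      bi <- min(max(bi, -C), C)
      d <- bi - beta[i]
      if (d != 0) {
        beta[i] <- bi
        r <- r + d * K[, i]
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < hyper$tol * C) break
  }
  list(beta = beta, gamma = gamma, sv = X, center = st$center,
       scale = st$scale, passes = pass)
}

.predict_svr <- function(object, x) {
  Xs <- scale(x, object$center, object$scale)
  Kx <- .rbf_kernel(Xs, object$sv, object$gamma) + 1
  drop(Kx %*% object$beta)
}

# ---- tree ensembles --------------------------------------------------------

# Both ensembles share the compiled gradient/hessian tree.  The forest
# grows least-squares CART trees (g = -y, h = 1, no regularisation) on
# bootstrap resamples and averages them; boosting fits each depth-4 tree
# to the current residual gradient with L1/L2-regularised leaf weights
# and shrinks it by the learning rate.  A fitted ensemble is a list of
# trees plus `base` and `scale`, with prediction
# base + scale * sum(tree predictions); leaf values already include the
# learning rate for boosting.

.fit_rf <- function(x, y, hyper, seed) {
  n <- nrow(x)
  set.seed(seed)
  trees <- vector("list", hyper$n_estimators)
  for (t in seq_along(trees)) {
    rows <- sample.int(n, n, replace = TRUE) - 1L
    trees[[t]] <- .cpp_build_tree(x, -y, rep(1, n), rows,
                                  hyper$max_depth, 1, 0, 0)
  }
  list(trees = trees, base = 0, tree_scale = 1 / length(trees))
}

.fit_xgb <- function(x, y, hyper, seed) {
  n <- nrow(x)
  base <- mean(y)
  pred <- rep(base, n)
  rows <- seq_len(n) - 1L
  trees <- vector("list", hyper$n_estimators)
  for (t in seq_along(trees)) {
    g <- pred - y
    h <- rep(1, n)
    tree <- .cpp_build_tree(x, g, h, rows, hyper$max_depth, 1,
                            hyper$reg_lambda, hyper$reg_alpha)
    tree$value <- tree$value * hyper$learning_rate
    pred <- pred + .cpp_predict_tree(tree, x)
    trees[[t]] <- tree
  }
  list(trees = trees, base = base, tree_scale = 1)
}

.predict_forest <- function(object, x) {
  out <- rep(object$base, nrow(x))
  for (tree in object$trees)
    out <- out + object$tree_scale * .cpp_predict_tree(tree, x)
  out
}

# ---- neural network --------------------------------------------------------

# Single-hidden-layer perceptron (ReLU, linear output) trained by
# minibatch Adam on the halved squared error with a small L2 penalty,
# following common MLP-regressor conventions: Glorot-uniform
# initialisation, batch size min(200, n), adaptive learning-rate schedule
# (divide by 5 after two consecutive epochs without a loss improvement
# of at least `tol`), stopping after 10 stagnant epochs, when the rate
# underflows 1e-6, or at `max_iter` epochs.

.fit_nn <- function(x, y, hyper, seed) {
  st <- .standardise(x)
  X <- st$x
  n <- nrow(X); p <- ncol(X); hdim <- hyper$hidden
  set.seed(seed)
  lim1 <- sqrt(6 / (p + hdim)); lim2 <- sqrt(6 / (hdim + 1))
  W1 <- matrix(stats::runif(p * hdim, -lim1, lim1), p, hdim)
  b1 <- numeric(hdim)
  W2 <- matrix(stats::runif(hdim, -lim2, lim2), hdim, 1)
  b2 <- 0
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(params, function(z) z * 0)
  vel <- lapply(params, function(z) z * 0)
  lr <- hyper$lr_init
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  batch <- min(hyper$batch_size, n)
  best <- Inf; stagnant <- 0L; step <- 0L
  converged <- FALSE
  for (epoch in seq_len(hyper$max_iter)) {
    idx <- sample.int(n)
    loss_sum <- 0
    for (start in seq(1, n, by = batch)) {
      rows <- idx[start:min(start + batch - 1L, n)]
      xb <- X[rows, , drop = FALSE]
      yb <- y[rows]
      m <- length(rows)
      z1 <- sweep(xb %*% params$W1, 2, params$b1, "+")
      a1 <- pmax(z1, 0)
      out <- drop(a1 %*% params$W2) + params$b2
      err <- out - yb
      loss_sum <- loss_sum + sum(err^2) / 2
      gout <- matrix(err / m, ncol = 1)
      gW2 <- crossprod(a1, gout) + hyper$alpha * params$W2
      gb2 <- sum(gout)
      ga1 <- tcrossprod(gout, params$W2) * (z1 > 0)
      gW1 <- crossprod(xb, ga1) + hyper$alpha * params$W1
      gb1 <- colSums(ga1)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      step <- step + 1L
      for (nm in names(params)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - beta1^step)
        vhat <- vel[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    loss <- loss_sum / n
    if (loss < best - hyper$tol) {
      best <- loss; stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (identical(hyper$learning_rate, "adaptive") && stagnant %% 2L == 0L)
        lr <- lr / 5
    }
    if (stagnant >= 10L || lr < 1e-6) { converged <- TRUE; break }
  }
  if (!converged && epoch == hyper$max_iter)
    message("NN: maximum iterations (", hyper$max_iter,
            ") reached without convergence")
  list(W1 = params$W1, b1 = params$b1, W2 = params$W2, b2 = params$b2,
       center = st$center, scale = st$scale, epochs = epoch,
       final_loss = loss)
}

.predict_nn <- function(object, x) {
  Xs <- scale(x, object$center, object$scale)
  a1 <- pmax(sweep(Xs %*% object$W1, 2, object$b1, "+"), 0)
  drop(a1 %*% object$W2) + object$b2
}
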