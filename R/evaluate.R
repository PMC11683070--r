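# Evaluation metrics, k-fold cross-validation and the benchmark sweep.

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; may be negative for
#' fits worse than the mean predictor.
#'
#' @param actual,predicted numeric vectors of equal length >= 2.
#' @return R-squared.
#' @export
r_squared <- function(actual, predicted) {
  .check_metric_args(actual, predicted)
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0)
    stop("r2 undefined: zero-variance actual values", call. = FALSE)
  1 - sum((actual - predicted)^2) / sst
}

#' Root mean square error
#' @inheritParams r_squared
#' @return RMSE in the units of the target.
#' @export
rmse <- function(actual, predicted) {
  .check_metric_args(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' Relative root mean square error
#'
#' RMSE divided by the mean of the actual values, as a percentage.
#' @inheritParams r_squared
#' @return RRMSE in percent.
#' @export
rrmse <- function(actual, predicted) {
  .check_metric_args(actual, predicted)
  ybar <- mean(actual)
  if (ybar == 0)
    stop("rrmse undefined: zero-mean actual values", call. = FALSE)
  100 * rmse(actual, predicted) / ybar
}

.check_metric_args <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 2L)
    stop("need equal-length vectors with n >= 2", call. = FALSE)
  if (any(!is.finite(actual)) || any(!is.finite(predicted)))
    stop("non-finite values in metric input", call. = FALSE)
}

#' All three evaluation metrics at once
#' @inheritParams r_squared
#' @return list with `r2`, `rmse`, `rrmse`.
#' @export
evaluation_metrics <- function(actual, predicted) {
  list(r2 = r_squared(actual, predicted),
       rmse = rmse(actual, predicted),
       rrmse = rrmse(actual, predicted))
}

#' Random k-fold assignment
#'
#' Folds partition the rows (disjoint, exhaustive) with sizes differing
#' by at most one; assignment is a seeded random permutation.
#'
#' @param n number of rows.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..k.
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  if (n < k) stop("insufficient data: fewer rows than folds", call. = FALSE)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' k-fold cross-validation of one model on one feature set
#'
#' Fits the configured model on k-1 folds and predicts the held-out fold,
#' for each fold in turn.  Training metrics are the across-fold average
#' of in-fold metrics; validation metrics are computed once on the pooled
#' out-of-fold predictions.  Deterministic given `seed` (fold assignment
#' and every model-internal RNG are derived from it).
#'
#' @param config a [model_config()].
#' @param features feature table (matrix or data.frame).
#' @param target numeric target vector.
#' @param k folds (default 10).
#' @param seed integer seed.
#' @return a `cv_result` list: `model`, `fold_assignments`,
#'   `oof_predictions`, `train_metrics`, `validation_metrics`.
#' @export
cross_validate <- function(config, features, target, k = 10L, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as.numeric(target)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("validation error: non-finite features or target", call. = FALSE)
  n <- nrow(x)
  folds <- make_folds(n, k, seed)
  oof <- rep(NA_real_, n)
  train_m <- matrix(NA_real_, k, 3,
                    dimnames = list(NULL, c("r2", "rmse", "rrmse")))
  for (f in seq_len(k)) {
    tr <- folds != f
    cfg <- config
    cfg$seed <- as.integer((seed * 131L + f) %% .Machine$integer.max)
    fit <- fit_model(cfg, x[tr, , drop = FALSE], y[tr])
    fit_tr <- predict(fit, x[tr, , drop = FALSE])
    m <- evaluation_metrics(y[tr], fit_tr)
    train_m[f, ] <- c(m$r2, m$rmse, m$rrmse)
    oof[!tr] <- predict(fit, x[!tr, , drop = FALSE])
  }
  val <- evaluation_metrics(y, oof)
  structure(list(model = config, k = k, seed = seed,
                 fold_assignments = folds, oof_predictions = oof,
                 train_metrics = as.list(colMeans(train_m)),
                 validation_metrics = val),
            class = "cv_result")
}

#' Full benchmark sweep
#'
#' Runs every multi-variable model family over every feature combination
#' and target under k-fold cross-validation, plus the single-variable LR
#' and QCR baselines on each channel mean (in-sample, mirroring the
#' exploratory per-channel regressions).  Targets: LNC and PNC are taken
#' from the observation table; NNI is computed from PNC, biomass and the
#' supplied dilution curve.
#'
#' @param obs plot-observation table (see [read_dataset()]).
#' @param targets subset of `c("LNC", "PNC", "NNI")`.
#' @param combos subset of `c("Chl", "Flav", "NBI", "All")`.
#' @param models subset of `c("PLS", "SVR", "RF", "XGB", "NN")`.
#' @param curve dilution curve for the NNI target (default published).
#' @param k CV folds (default 10).
#' @param seed integer seed.
#' @param simple_baselines also fit LR/QCR per channel mean (default TRUE).
#' @return list with `results` (long data.table: target, combo, model,
#'   split, r2, rmse, rrmse) and `cv` (nested cv_result objects keyed
#'   `target.combo.model`).
#' @export
run_benchmark <- function(obs,
                          targets = c("LNC", "PNC", "NNI"),
                          combos = c("Chl", "Flav", "NBI", "All"),
                          models = c("PLS", "SVR", "RF", "XGB", "NN"),
                          curve = published_curve(),
                          k = 10L, seed = 1L,
                          simple_baselines = TRUE) {
  obs <- validate_observations(obs)
  targets <- match.arg(targets, c("LNC", "PNC", "NNI"), several.ok = TRUE)
  combos <- match.arg(combos, c("Chl", "Flav", "NBI", "All"),
                      several.ok = TRUE)
  models <- match.arg(models, c("PLS", "SVR", "RF", "XGB", "NN"),
                      several.ok = TRUE)
  ft <- feature_table(obs)
  combo_tabs <- build_feature_combinations(ft)[combos]
  tvals <- list(LNC = obs$lnc, PNC = obs$pnc,
                NNI = compute_nni(obs$pnc, critical_n(obs$biomass_w, curve)))
  rows <- list(); cvs <- list()
  for (tg in targets) {
    y <- tvals[[tg]]
    for (cb in combos) {
      for (md in models) {
        cv <- cross_validate(model_config(md, seed), combo_tabs[[cb]], y,
                             k = k, seed = seed)
        key <- paste(tg, cb, md, sep = ".")
        cvs[[key]] <- cv
        rows[[length(rows) + 1L]] <- data.table::data.table(
          target = tg, combo = cb, model = md,
          split = c("train", "validation"),
          r2 = c(cv$train_metrics$r2, cv$validation_metrics$r2),
          rmse = c(cv$train_metrics$rmse, cv$validation_metrics$rmse),
          rrmse = c(cv$train_metrics$rrmse, cv$validation_metrics$rrmse))
      }
    }
    if (simple_baselines) {
      for (ch in c("Chl", "Flav", "NBI")) {
        xm <- ft[[paste0(ch, "_mean")]]
        for (md in c("LR", "QCR")) {
          fit <- fit_simple_regression(xm, y, md)
          rows[[length(rows) + 1L]] <- data.table::data.table(
            target = tg, combo = paste0(ch, "_mean"), model = md,
            split = "in_sample", r2 = fit$metrics$r2,
            rmse = fit$metrics$rmse, rrmse = fit$metrics$rrmse)
        }
      }
    }
  }
  list(results = data.table::rbindlist(rows), cv = cvs)
}
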