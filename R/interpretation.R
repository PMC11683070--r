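# Shapley-value feature attribution for the tree ensembles.
#
# Attributions use the interventional expectation: the value of a
# coalition S is the mean model output over background rows whose
# S-features are replaced by the explained sample's values.  For a tree
# this expectation is computed exactly by the compiled per-reference
# recursion (src/trees.cpp); a brute-force coalition-enumeration oracle
# with the same value function is provided for verification on small
# feature counts.

#' Shapley attributions for a fitted tree ensemble
#'
#' Exact interventional Shapley values per sample and feature for a
#' fitted random forest or gradient-boosting model.  The background set
#' is capped at `max_background` rows by a seeded subsample.  Additivity
#' holds exactly: for every sample, `base_value + sum(attributions)`
#' equals the model prediction.
#'
#' @param model fitted `nsat_model` of family RF or XGB.
#' @param features rows to explain (matrix/data.frame, training columns).
#' @param background reference rows (typically the training data).
#' @param max_background cap on background rows (default 200).
#' @param seed seed for the background subsample.
#' @return an `attribution_report`: `model` label, `values` (sample x
#'   feature matrix), `base_value`, `ranking` (features by decreasing
#'   mean |value|), `mean_abs` named vector.
#' @export
attribute <- function(model, features, background, max_background = 200L,
                      seed = 1L) {
  if (!inherits(model, "nsat_model") || !model$family %in% c("RF", "XGB"))
    stop("state error: attribution requires a fitted RF or XGB model",
         call. = FALSE)
  x <- as.matrix(features); storage.mode(x) <- "double"
  bg <- as.matrix(background); storage.mode(bg) <- "double"
  if (nrow(bg) == 0L) stop("empty background", call. = FALSE)
  if (nrow(bg) > max_background) {
    set.seed(seed)
    bg <- bg[sample.int(nrow(bg), max_background), , drop = FALSE]
  }
  phi <- matrix(0, nrow(x), ncol(x))
  for (tree in model$trees)
    phi <- phi + model$tree_scale * .cpp_tree_shap(tree, x, bg)
  colnames(phi) <- colnames(x)
  base <- mean(predict(model, bg))
  mean_abs <- colMeans(abs(phi))
  # stable tie-break by column order
  ord <- order(-mean_abs, seq_along(mean_abs))
  ranking <- colnames(phi)[ord]
  structure(list(model = model$family, values = phi, base_value = base,
                 ranking = ranking, mean_abs = mean_abs),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("Attribution report (%s): %d samples x %d features\n",
              x$model, nrow(x$values), ncol(x$values)))
  cat("Top features:", paste(utils::head(x$ranking, 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' Brute-force Shapley oracle
#'
#' Classical Shapley values by full coalition enumeration (2^p subsets),
#' with the interventional value function: v(S) is the mean of
#' `predict_fn` over background rows whose S-columns are set to the
#' sample's values.  Refuses more than 10 features.
#'
#' @param predict_fn function taking a numeric matrix, returning
#'   predictions.
#' @param sample single row to explain (numeric vector).
#' @param background background matrix (columns as in `sample`).
#' @return numeric attribution vector (one value per feature).
#' @export
shapley_oracle <- function(predict_fn, sample, background) {
  bg <- as.matrix(background)
  p <- ncol(bg)
  if (p > 10L)
    stop("refusing brute-force enumeration for p > 10 features",
         call. = FALSE)
  sample <- as.numeric(sample)
  nmask <- bitwShiftL(1L, p)
  v <- numeric(nmask)
  for (m in seq_len(nmask) - 1L) {
    z <- bg
    for (j in seq_len(p))
      if (bitwAnd(m, bitwShiftL(1L, j - 1L)) != 0L) z[, j] <- sample[j]
    v[m + 1L] <- mean(predict_fn(z))
  }
  fact <- factorial(0:p)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (m in seq_len(nmask) - 1L) {
      if (bitwAnd(m, bit) != 0L) next
      s <- sum(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      w <- fact[s + 1L] * fact[p - s] / fact[p + 1L]
      phi[j] <- phi[j] + w * (v[bitwOr(m, bit) + 1L] - v[m + 1L])
    }
  }
  phi
}

#' Rank features by mean absolute attribution
#'
#' @param report an `attribution_report` from [attribute()].
#' @param top_k how many features to tabulate (default 15).
#' @return data.table with `feature`, `mean_abs_shap`, in descending
#'   order (ties broken by column order); attribute `ranking` holds the
#'   full ordered feature list.
#' @export
rank_features <- function(report, top_k = 15L) {
  stopifnot(inherits(report, "attribution_report"))
  ord <- order(-report$mean_abs, seq_along(report$mean_abs))
  tab <- data.table::data.table(
    feature = colnames(report$values)[ord],
    mean_abs_shap = unname(report$mean_abs[ord]))
  structure(utils::head(tab, top_k), ranking = tab$feature)
}
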