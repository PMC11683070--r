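# Critical nitrogen dilution curve and the Nitrogen Nutrition Index.
#
# The critical concentration Nc (% N) is the minimum plant N allowing
# maximum growth at a given above-ground dry matter W (t/ha), modelled as
# the power law Nc = a * W^(-b).  The published rice curve used as a
# default throughout the package is a = 3.44, b = 0.43.  NNI = PNC / Nc;
# > 1 surplus, = 1 sufficiency, < 1 deficiency.

#' Published rice critical dilution curve
#'
#' Convenience constructor for the reference curve Nc = 3.44 * W^(-0.43).
#' @return a `dilution_curve` object.
#' @export
published_curve <- function() dilution_curve(3.44, 0.43, n_support = NA_integer_)

#' Dilution-curve object
#'
#' @param a coefficient: % N at W = 1 t/ha; must be > 0.
#' @param b positive dilution exponent (the curve is `a * W^(-b)`).
#' @param n_support number of boundary points behind the fit.
#' @return a `dilution_curve` list with fields `a`, `b`, `n_support`.
#' @export
dilution_curve <- function(a, b, n_support = NA_integer_) {
  if (!is.finite(a) || a <= 0) stop("dilution curve needs a > 0", call. = FALSE)
  if (!is.finite(b) || b <= 0)
    stop("degenerate dilution curve: exponent must be > 0 (flat or rising ",
         "N-biomass relation)", call. = FALSE)
  structure(list(a = a, b = b, n_support = n_support),
            class = "dilution_curve")
}

#' @export
print.dilution_curve <- function(x, ...) {
  cat(sprintf("Critical N dilution curve: Nc = %.4g * W^(-%.4g)", x$a, x$b))
  if (!is.na(x$n_support)) cat(sprintf("  [%d boundary points]", x$n_support))
  cat("\n")
  invisible(x)
}

#' Fit a critical dilution curve to the minimum-N boundary
#'
#' Bins observations by biomass quantiles; within each bin holding at
#' least `min_bin_count` points the boundary point is the bin's
#' minimum-PNC observation, i.e. the pair (W at the minimum, minimum
#' PNC); the power law is then fitted by ordinary least squares in
#' log-log space, `log(PNC_min) = log a - b log W`, which is exact for
#' power laws and needs no initialisation.  Taking the minimum point's
#' own biomass as the abscissa (rather than a bin summary such as the
#' median W) makes the fit exact when the boundary observations lie on a
#' power law.
#'
#' The boundary-minimum construction presumes the input contains, at
#' every biomass level, crops that are not nitrogen-limited in excess
#' (i.e. the lower envelope of the cloud IS the critical curve).  When
#' fitting to a whole trial including deficient treatments, pass only the
#' non-limited subset.  Observations with `w < w_floor` are excluded
#' (very early, pre-dilution samples).
#'
#' @param w above-ground dry biomass, t/ha, > 0.
#' @param pnc plant N concentration, % dry mass, > 0.
#' @param n_bins number of biomass quantile bins (default 8).
#' @param min_bin_count minimum points for a bin to contribute (default 5).
#' @param w_floor biomass floor, t/ha (default 0.5).
#' @return a [dilution_curve()] with `n_support` = number of bins used.
#' @export
fit_dilution_curve <- function(w, pnc, n_bins = 8L, min_bin_count = 5L,
                               w_floor = 0.5) {
  if (length(w) != length(pnc)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(w) & is.finite(pnc) & w > 0 & pnc > 0
  if (!all(ok)) stop("w and pnc must be finite and > 0", call. = FALSE)
  keep <- w >= w_floor
  w <- w[keep]; pnc <- pnc[keep]
  if (length(w) < 2L * n_bins)
    stop("insufficient support: need at least 2 points per bin", call. = FALSE)
  br <- stats::quantile(w, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE)
  br <- unique(br)
  bin <- cut(w, breaks = br, include.lowest = TRUE, labels = FALSE)
  idx_min <- tapply(seq_along(pnc), bin, function(i) i[which.min(pnc[i])])
  wb <- w[idx_min]
  pb <- pnc[idx_min]
  cnt <- tabulate(bin)
  use <- cnt[as.integer(names(idx_min))] >= min_bin_count
  wb <- wb[use]; pb <- pb[use]
  if (length(wb) < 2L)
    stop("insufficient support: fewer than 2 usable bins", call. = FALSE)
  fit <- stats::lsfit(log(wb), log(pb))
  a <- exp(fit$coefficients[["Intercept"]])
  b <- -fit$coefficients[["X"]]
  dilution_curve(a, b, n_support = length(wb))
}

#' Critical nitrogen concentration at a given biomass
#'
#' Evaluates Nc = a * W^(-b); strictly decreasing in W (nitrogen
#' dilution).
#'
#' @param w above-ground dry matter, t/ha, > 0 (vectorised).
#' @param curve a [dilution_curve()]; default the published rice curve.
#' @return Nc in % dry mass.
#' @export
critical_n <- function(w, curve = published_curve()) {
  stopifnot(inherits(curve, "dilution_curve"))
  if (any(!is.finite(w)) || any(w <= 0))
    stop("domain error: biomass must be finite and > 0", call. = FALSE)
  curve$a * w^(-curve$b)
}

#' Nitrogen Nutrition Index
#'
#' NNI = PNC / Nc.  Values above 1 indicate nitrogen surplus, 1
#' sufficiency, below 1 deficiency.
#'
#' @param pnc plant N concentration, % dry mass.
#' @param nc critical N concentration, % dry mass, > 0.
#' @return NNI values (vectorised).
#' @export
compute_nni <- function(pnc, nc) {
  if (any(!is.finite(nc)) || any(nc <= 0))
    stop("degenerate denominator: Nc must be finite and > 0", call. = FALSE)
  pnc / nc
}

#' Classify NNI values
#'
#' @param nni NNI values.
#' @param tol half-width of the sufficiency band around 1 (default 1e-9).
#' @return character vector: "surplus", "sufficiency" or "deficiency".
#' @export
classify_nni <- function(nni, tol = 1e-9) {
  ifelse(abs(nni - 1) <= tol, "sufficiency",
         ifelse(nni > 1, "surplus", "deficiency"))
}

#' Append Nc, NNI and its class to a plot-observation table
#'
#' @param obs plot observations (see [read_dataset()]).
#' @param curve a [dilution_curve()]; default the published rice curve.
#' @return copy of `obs` with `nc`, `nni`, `nni_class` columns.
#' @export
annotate_nni <- function(obs, curve = published_curve()) {
  obs <- validate_observations(obs)
  out <- data.table::copy(obs)
  out[, "nc" := critical_n(out$biomass_w, curve)]
  out[, "nni" := compute_nni(out$pnc, out$nc)]
  out[, "nni_class" := classify_nni(out$nni)]
  out[]
}
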