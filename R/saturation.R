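# Incremental rate-of-change analysis of sensor saturation.
#
# The diagnostic asks: does the sensor index X keep responding as the
# nitrogen status Y climbs into its upper range?  Both variables are
# min-max scaled, pairs are sorted by scaled X, adjacent increments give
# a rate dY/dX (increments with |dX| below a threshold are dropped as
# numerically unstable), rates are normalised by the maximum absolute
# rate and smoothed with a centred 5-point moving average.  Separately, a
# Gaussian kernel density over the scaled X values of the top 20% of Y
# localises where the best-nourished plants sit on the sensor scale: a
# density peak well below 1 means the index stops discriminating at high
# N (saturation), a peak near the upper boundary means it keeps
# discriminating.

#' Parameters of the saturation analysis
#'
#' @param dx_threshold minimum |dX| (on the scaled axis) for a rate to be
#'   computed; smaller increments yield NaN rates (default 1e-3).
#' @param smooth_window odd moving-average window (default 5).
#' @param top_fraction share of the highest Y values examined by the
#'   density step (default 0.20).
#' @param kde_bandwidth "scott" (default: sd * n^(-1/5)) or a positive
#'   number on the scaled X axis.
#' @param grid_points density evaluation grid size over \[0, 1\]
#'   (default 512).
#' @return a `saturation_params` list.
#' @export
saturation_params <- function(dx_threshold = 1e-3, smooth_window = 5L,
                              top_fraction = 0.20, kde_bandwidth = "scott",
                              grid_points = 512L) {
  if (dx_threshold <= 0) stop("dx_threshold must be > 0", call. = FALSE)
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop("parameter error: smooth_window must be odd and >= 1", call. = FALSE)
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must be in (0, 1)", call. = FALSE)
  if (is.numeric(kde_bandwidth) && kde_bandwidth <= 0)
    stop("kde_bandwidth must be positive", call. = FALSE)
  structure(list(dx_threshold = dx_threshold,
                 smooth_window = as.integer(smooth_window),
                 top_fraction = top_fraction, kde_bandwidth = kde_bandwidth,
                 grid_points = as.integer(grid_points)),
            class = "saturation_params")
}

#' Min-max scale to the unit interval
#'
#' @param v numeric vector with at least two distinct finite values.
#' @return `(v - min) / (max - min)`; the minimum maps to 0, the maximum
#'   to 1.
#' @export
minmax_scale <- function(v) {
  if (any(!is.finite(v))) stop("non-finite values", call. = FALSE)
  rng <- range(v)
  if (diff(rng) == 0)
    stop("degenerate range: constant vector cannot be min-max scaled",
         call. = FALSE)
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Incremental rates of change of Y with respect to X
#'
#' Scales both variables to \[0, 1\], sorts pairs by scaled X (stable:
#' ties keep input order), forms adjacent increments dX_i, dY_i, and the
#' rate dY_i/dX_i wherever |dX_i| >= `dx_threshold` (NaN otherwise).
#' Rates are normalised to \[-1, 1\] by the maximum finite absolute rate.
#'
#' @param x sensor index values (length >= 3, >= 2 distinct).
#' @param y nitrogen status values, same length.
#' @param params a [saturation_params()].
#' @return list with `x_scaled`, `y_scaled` (sorted), `dx`, `dy`, `rate`,
#'   `rate_scaled` (all length n-1).
#' @export
incremental_rates <- function(x, y, params = saturation_params()) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length x and y with n >= 3", call. = FALSE)
  xs <- minmax_scale(x)
  ys <- minmax_scale(y)
  ord <- order(xs)                      # radix sort: stable on ties
  xs <- xs[ord]; ys <- ys[ord]
  dx <- diff(xs); dy <- diff(ys)
  rate <- ifelse(abs(dx) >= params$dx_threshold, dy / dx, NaN)
  if (all(is.nan(rate)))
    stop("no valid increments: all |dX| below threshold", call. = FALSE)
  m <- max(abs(rate), na.rm = TRUE)
  rate_scaled <- if (m > 0) rate / m else rate
  list(x_scaled = xs, y_scaled = ys, dx = dx, dy = dy,
       rate = rate, rate_scaled = rate_scaled)
}

#' Centred moving average with shrinking edges
#'
#' Mean over a centred window of odd width; positions whose window would
#' extend past either end use the truncated window (no padding).  NaN
#' entries are excluded from each window's mean; an all-NaN window yields
#' NaN.
#'
#' @param v numeric vector, possibly containing NaN.
#' @param window odd window width >= 1.
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(v, window = 5L) {
  if (window < 1L || window %% 2L == 0L)
    stop("parameter error: window must be odd and >= 1", call. = FALSE)
  n <- length(v)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    wnd <- v[max(1L, i - half):min(n, i + half)]
    wnd <- wnd[!is.nan(wnd)]
    out[i] <- if (length(wnd)) mean(wnd) else NaN
  }
  out
}

#' Density of scaled X among the top fraction of Y
#'
#' Selects rows whose scaled Y lies in the top `top_fraction` of the
#' scaled range (`y_scaled >= 1 - top_fraction`) and estimates a Gaussian
#' kernel density of their scaled X values on a uniform grid over
#' \[0, 1\].  The argmax locates where the highest-nitrogen samples sit
#' on the sensor scale: a non-saturating sensor confines them to the top
#' of its own scale (peak near 1); a saturating sensor spreads them over
#' a wide span, pulling the peak down.  Selection is by position in the
#' scaled range, not by sample quantile: for a flat (saturated) response
#' many samples share near-maximal Y, and exactly that excess mass is
#' the diagnostic.
#'
#' @param x_scaled,y_scaled unit-interval vectors (same length).
#' @param params a [saturation_params()].
#' @return list with `density_x` (grid), `density` (values), `peak_x`
#'   (argmax), `degenerate` (TRUE when the subset has a single distinct
#'   X, in which case that X is returned as the peak).
#' @export
top_fraction_density <- function(x_scaled, y_scaled,
                                 params = saturation_params()) {
  xt <- x_scaled[y_scaled >= 1 - params$top_fraction]
  grid <- seq(0, 1, length.out = params$grid_points)
  if (length(unique(xt)) < 2L) {
    if (length(xt) == 0L) stop("empty top-fraction subset", call. = FALSE)
    return(list(density_x = grid, density = rep(NaN, length(grid)),
                peak_x = xt[1], degenerate = TRUE, n_top = length(xt)))
  }
  if (length(xt) < 5L)
    warning("top-fraction subset has fewer than 5 points")
  h <- if (identical(params$kde_bandwidth, "scott"))
    stats::sd(xt) * length(xt)^(-1 / 5) else params$kde_bandwidth
  dens <- vapply(grid,
                 function(g) mean(stats::dnorm((g - xt) / h)) / h,
                 numeric(1))
  list(density_x = grid, density = dens, peak_x = grid[which.max(dens)],
       degenerate = FALSE, n_top = length(xt))
}

#' Full incremental saturation analysis
#'
#' Composes [incremental_rates()], [moving_average()] and
#' [top_fraction_density()] into a saturation trace, and adds a scalar
#' summary: the mean absolute smoothed rate over the top quartile of
#' scaled X divided by the mean over the interquartile range.  Values
#' much below 1 indicate that the sensor stops responding at the top of
#' its range (saturation); a linear relation gives ~1.  The summary is a
#' package addition for programmatic comparison; the primary diagnostic
#' remains the density peak.
#'
#' @param x sensor index values.
#' @param y nitrogen status values.
#' @param params a [saturation_params()].
#' @return a `saturation_trace` list: the fields of [incremental_rates()]
#'   plus `rate_smoothed`, `density_x`, `density`, `peak_x`, `degenerate`
#'   and `summary_ratio`.
#' @export
run_saturation_analysis <- function(x, y, params = saturation_params()) {
  tr <- incremental_rates(x, y, params)
  tr$rate_smoothed <- moving_average(tr$rate_scaled, params$smooth_window)
  dens <- top_fraction_density(tr$x_scaled, tr$y_scaled, params)
  tr[names(dens)] <- dens
  xmid <- tr$x_scaled[-length(tr$x_scaled)]   # increment i sits at x_i
  rs <- abs(tr$rate_smoothed)
  top <- xmid >= 0.75 & !is.nan(rs)
  mid <- xmid >= 0.25 & xmid < 0.75 & !is.nan(rs)
  tr$summary_ratio <- if (any(top) && any(mid) && mean(rs[mid]) > 0)
    mean(rs[top]) / mean(rs[mid]) else NaN
  class(tr) <- "saturation_trace"
  tr
}

#' @export
print.saturation_trace <- function(x, ...) {
  cat(sprintf(
    "Saturation trace: n = %d, density peak at x = %.3f%s, summary ratio = %.3f\n",
    length(x$x_scaled), x$peak_x,
    if (isTRUE(x$degenerate)) " (degenerate)" else "", x$summary_ratio))
  invisible(x)
}
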