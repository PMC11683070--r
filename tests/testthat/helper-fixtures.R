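# Shared fixtures and independent reference (oracle) implementations.
# Everything is generated in code; no data files.

# a reduced trial layout (6 of the 15 varieties, one replicate) used
# where many repeated runs are needed
small_trial_config <- function(seed, ...) {
  trial_config(design = default_trial_design()[c(1, 4, 7, 9, 11, 14)],
               replicates = 1L, seed = seed, ...)
}

# tiny deterministic observation table built by hand (no RNG)
tiny_obs <- function(n = 10L) {
  stopifnot(n >= 1L)
  i <- seq_len(n)
  obs <- data.table::data.table(
    site = "S1", variety = paste0("V", (i %% 3) + 1), subspecies = "japonica",
    n_rate = 60 * (i %% 4), stage = rice_stages[(i %% 4) + 1],
    biomass_w = 1 + 0.7 * i, lnc = 2 + 0.1 * i, pnc = 1.5 + 0.08 * i)
  for (p in 1:5) {
    chl <- 20 + i + p
    flav <- 0.8 + 0.05 * i + 0.1 * p
    data.table::set(obs, j = paste0("chl_l", p), value = chl)
    data.table::set(obs, j = paste0("flav_l", p), value = flav)
    data.table::set(obs, j = paste0("nbi_l", p), value = chl / flav)
  }
  obs[, "leaf5_imputed" := 0L]
  obs[]
}

# naive loop reference for the incremental-rate pipeline (no
# vectorisation; mirrors the five analysis steps literally)
naive_rate_pipeline <- function(x, y, dx_threshold = 1e-3) {
  sx <- (x - min(x)) / (max(x) - min(x))
  sy <- (y - min(y)) / (max(y) - min(y))
  ord <- order(sx)                       # stable
  sx <- sx[ord]; sy <- sy[ord]
  n <- length(sx)
  rate <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    dx <- sx[i + 1] - sx[i]
    dy <- sy[i + 1] - sy[i]
    rate[i] <- if (abs(dx) >= dx_threshold) dy / dx else NaN
  }
  mx <- 0
  for (i in seq_along(rate))
    if (!is.nan(rate[i]) && abs(rate[i]) > mx) mx <- abs(rate[i])
  out <- numeric(length(rate))
  for (i in seq_along(rate)) out[i] <- rate[i] / mx
  out
}

# naive loop reference for the evaluation metrics
naive_metrics <- function(a, p) {
  n <- length(a)
  sse <- 0; sst <- 0; ab <- 0
  for (i in seq_len(n)) ab <- ab + a[i] / n
  for (i in seq_len(n)) {
    sse <- sse + (a[i] - p[i])^2
    sst <- sst + (a[i] - ab)^2
  }
  list(r2 = 1 - sse / sst, rmse = sqrt(sse / n),
       rrmse = 100 * sqrt(sse / n) / ab)
}

# boundary-point cloud whose per-bin minimum PNC lies exactly on the
# dilution curve (the t1/t2 construction): sample biomass, assign
# quantile bins, put one on-curve point per bin and lift the rest by
# positive offsets large enough never to undercut the designated minimum
boundary_cloud <- function(n = 500L, a = 3.44, b = 0.43, n_bins = 8L,
                           w_range = c(1, 12)) {
  w <- stats::runif(n, w_range[1], w_range[2])
  nc <- a * w^(-b)
  br <- stats::quantile(w, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  bin <- cut(w, breaks = br, include.lowest = TRUE, labels = FALSE)
  pnc <- numeric(n)
  for (bb in seq_len(n_bins)) {
    idx <- which(bin == bb)
    gap <- diff(range(nc[idx]))          # max in-bin decline of the curve
    off <- stats::runif(length(idx), gap + 0.05, gap + 1.0)
    pnc[idx] <- nc[idx] + off
    keep <- idx[which.min(abs(w[idx] - stats::median(w[idx])))]
    pnc[keep] <- nc[keep]                # designated on-curve minimum
  }
  list(w = w, pnc = pnc)
}
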