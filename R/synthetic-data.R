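# Synthetic field-trial generator.
#
# Emulates the structure of a multi-site rice nitrogen-rate experiment:
# 15 varieties over 4 sites, each with its own ladder of 3-6 nitrogen
# rates, sampled at successive growth stages.  The generating model is a
# stated world: plant N follows the critical dilution curve scaled by a
# target NNI that increases with the nitrogen rate; the chlorophyll
# channel is a saturating map of leaf N while the flavonoid channel is an
# (inverse) affine map, so downstream saturation diagnostics have a known
# answer.

#' Default multi-site trial design
#'
#' The factorial layout used by [trial_config()]: 15 varieties (10
#' japonica, 4 indica, 1 indica-japonica hybrid) across four sites, each
#' variety with its own nitrogen-rate ladder of 3-6 rates (kg N/ha)
#' including an unfertilised control.
#'
#' @return data.table with columns `variety`, `subspecies`, `site` and a
#'   list column `rates`.
#' @export
default_trial_design <- function() {
  data.table::data.table(
    variety = c("NG3908", "NG5055", "NG46", "YG13", "NG3", "JH218",
                "JYZK6", "XS14", "YY15", "J67", "HHZ", "MXXZ", "CY5",
                "TYXZ", "TYHZ"),
    subspecies = c(rep("japonica", 8), "hybrid", "japonica",
                   "indica", "indica", "japonica", "indica", "indica"),
    site = c("Nanjing", "Nanjing", "Zhenjiang", "Zhenjiang", "Zhenjiang",
             rep("Jiaxing", 5), rep("Yichun", 5)),
    rates = list(
      c(0, 60, 120, 180, 240, 300), c(0, 100, 150, 200, 250, 300),
      c(0, 60, 120, 180, 240, 300), c(0, 75, 150, 225, 300),
      c(0, 75, 150, 225, 300), c(0, 80, 120, 140, 160),
      c(0, 200, 300), c(0, 100, 200), c(0, 189, 230, 270),
      c(0, 127, 169), c(0, 135, 180, 225), c(0, 135, 180, 225),
      c(0, 135, 180, 225), c(0, 135, 180, 225), c(0, 135, 180, 225)
    )
  )
}

#' Configuration for the synthetic trial generator
#'
#' All defaults describe the emulated experiment; they are documented in
#' the methods vignette and are not tuned per analysis.
#'
#' @param design trial layout (variety x site x rate ladder), default
#'   [default_trial_design()].  Alternatively pass `n_sites`,
#'   `varieties_per_site` and `n_rates` to build a regular factorial.
#' @param n_sites,varieties_per_site,n_rates regular-factorial shortcut,
#'   used only when `design` is NULL.
#' @param stages ordered subset of [rice_stages] sampled per plot.
#' @param replicates replicate plots per variety x rate.
#' @param seed integer RNG seed; generation is deterministic given it.
#' @param noise_sd relative (lognormal) sensor noise for leaf 1; deeper
#'   leaves are noisier by `noise_position_scale`.
#' @param lab_noise_sd relative noise of the Kjeldahl N determinations.
#' @param curve_a,curve_b critical dilution curve Nc = a * W^(-b) used as
#'   ground truth (defaults 3.44, 0.43).
#' @param chl_max,chl_k saturating chlorophyll response parameters, see
#'   [chl_response()].
#' @param flav_intercept,flav_slope,flav_floor flavonoid response, see
#'   [flav_response()].
#' @param chl_stage_gain multiplicative stage effect on the chlorophyll
#'   response (TI..GF): per-area chlorophyll is lower in young, thin
#'   leaves at equal mass-based leaf N, so tillering-stage readings sit
#'   below later-stage readings.  This stage dependence, together with
#'   the saturating response, is what makes chlorophyll unreliable at
#'   high nitrogen: high-N early-stage plants overlap moderate-N
#'   late-stage plants on the Chl scale.  The flavonoid channel carries
#'   no stage effect (its N response is stable across stages).
#' @param variety_cal_sd relative SD of a per-variety leaf-optics
#'   calibration factor (leaf thickness and surface structure), applied
#'   to both transmittance channels alike, so the Chl/Flav ratio (NBI)
#'   cancels it — the reason NBI is the most genotype-robust index.
#'   Scales with `noise_sd` like the other nuisance variation.
#' @param leaf_gradient_chl,leaf_gradient_flav multiplicative per-position
#'   profiles (top leaf first): Chl and NBI highest in top leaves, Flav
#'   highest in lower leaves.
#' @param leaf_signal_mix per-position weight of the current leaf N signal
#'   versus the plot's nitrogen history baseline; lower leaves track
#'   current N status less tightly (nitrogen translocation), so top
#'   leaves carry the cleanest signal.
#' @param leaf_history_sd relative SD of the per-plot nitrogen-history
#'   deviation carried by lower leaves (senescence and shading state
#'   shared by all leaves of a plot, hence not removed by averaging
#'   positions); scales with `noise_sd`.
#' @param noise_position_scale per-position multiplier on `noise_sd`;
#'   the fully expanded top leaves give the most repeatable clip
#'   readings, deeper positions are noisier.
#' @param nni_range target NNI at zero N and at the top rate.
#' @param stage_biomass typical above-ground dry matter (t/ha) per stage
#'   TI..GF; roughly geometric growth from 1 to beyond 12 t/ha.
#' @return a `trial_config` list.
#' @export
trial_config <- function(design = default_trial_design(),
                         n_sites = NULL, varieties_per_site = NULL,
                         n_rates = NULL,
                         stages = c("TI", "SE", "PI", "HD"),
                         replicates = 3L,
                         seed = 1L,
                         noise_sd = 0.05,
                         lab_noise_sd = 0.02,
                         curve_a = 3.44, curve_b = 0.43,
                         chl_max = 42, chl_k = 0.55,
                         flav_intercept = 2.8, flav_slope = 0.35,
                         flav_floor = 0.2,
                         chl_stage_gain = c(TI = 0.75, SE = 0.95, PI = 1.05,
                                            HD = 1.10, GF = 1.10),
                         variety_cal_sd = 0.04,
                         leaf_gradient_chl = c(1.15, 1.08, 1.00, 0.93, 0.87),
                         leaf_gradient_flav = c(0.87, 0.93, 1.00, 1.08, 1.15),
                         leaf_signal_mix = c(1.00, 0.95, 0.85, 0.70, 0.55),
                         leaf_history_sd = 0.25,
                         noise_position_scale = c(0.6, 0.75, 1.0, 1.4, 1.8),
                         nni_range = c(0.45, 1.35),
                         stage_biomass = c(TI = 1.0, SE = 2.3, PI = 5.2,
                                           HD = 12.0, GF = 13.5)) {
  if (is.null(design)) {
    if (is.null(n_sites) || is.null(varieties_per_site) || is.null(n_rates))
      stop("config error: give either a design or the factorial shortcut",
           call. = FALSE)
    if (n_sites < 1L || varieties_per_site < 1L || length(n_rates) < 1L)
      stop("config error: all counts must be >= 1", call. = FALSE)
    design <- data.table::CJ(site = paste0("S", seq_len(n_sites)),
                             vi = seq_len(varieties_per_site))
    design[, "variety" := paste0("V", .I)]
    design[, "subspecies" := "japonica"]
    design[, "vi" := NULL]
    design[, "rates" := list(list(n_rates))]
  }
  if (length(stages) == 0L || nrow(design) == 0L)
    stop("config error: empty stages or design", call. = FALSE)
  stages <- match.arg(stages, rice_stages, several.ok = TRUE)
  if (replicates < 1L) stop("config error: replicates >= 1", call. = FALSE)
  if (curve_a <= 0 || curve_b <= 0 || curve_b >= 1)
    stop("config error: need curve_a > 0 and 0 < curve_b < 1", call. = FALSE)
  if (noise_sd < 0 || lab_noise_sd < 0)
    stop("config error: noise levels must be >= 0", call. = FALSE)
  cfg <- list(design = data.table::as.data.table(design), stages = stages,
              replicates = as.integer(replicates), seed = as.integer(seed),
              noise_sd = noise_sd, lab_noise_sd = lab_noise_sd,
              curve_a = curve_a, curve_b = curve_b,
              chl_max = chl_max, chl_k = chl_k,
              flav_intercept = flav_intercept, flav_slope = flav_slope,
              flav_floor = flav_floor,
              chl_stage_gain = chl_stage_gain,
              variety_cal_sd = variety_cal_sd,
              leaf_gradient_chl = leaf_gradient_chl,
              leaf_gradient_flav = leaf_gradient_flav,
              leaf_signal_mix = leaf_signal_mix,
              leaf_history_sd = leaf_history_sd,
              noise_position_scale = noise_position_scale,
              nni_range = nni_range, stage_biomass = stage_biomass)
  class(cfg) <- "trial_config"
  cfg
}

#' Saturating chlorophyll response to leaf nitrogen
#'
#' Exponential-saturation map `chl = chl_max * (1 - exp(-k * lnc))`:
#' strictly increasing, bounded above by `chl_max`, with flattening
#' beginning in the 35-40 index range for the default parameters.
#'
#' @param lnc leaf N concentration (% dry mass), > 0.
#' @param chl_max asymptote of the chlorophyll index.
#' @param k curvature (per % N); larger k saturates earlier.
#' @return chlorophyll index values.
#' @export
chl_response <- function(lnc, chl_max = 42, k = 0.55) {
  chl_max * (1 - exp(-k * lnc))
}

#' Decreasing flavonoid response to leaf nitrogen
#'
#' Affine decrease `intercept - slope * lnc`, relaxed onto a positive
#' floor: below the floor the response keeps decreasing at 2% of the
#' nominal slope so the map stays strictly decreasing while remaining
#' effectively clipped.
#'
#' @param lnc leaf N concentration (% dry mass), > 0.
#' @param intercept flavonoid index extrapolated to zero leaf N.
#' @param slope index decrease per % leaf N.
#' @param floor lower bound of the affine segment.
#' @return flavonoid index values.
#' @export
flav_response <- function(lnc, intercept = 2.8, slope = 0.35, floor = 0.2) {
  raw <- intercept - slope * lnc
  ifelse(raw >= floor, raw, floor + 0.02 * (raw - floor))
}

#' Generate a synthetic field trial
#'
#' Simulates one plot observation per site x variety x nitrogen rate x
#' replicate x stage.  Biomass grows with stage and mildly with nitrogen
#' rate; a target NNI increases with rate (unfertilised plots well below
#' 1, the highest rates up to ~1.4); PNC follows from NNI and the
#' dilution curve; LNC is PNC times a leaf-enrichment factor; mean Chl and
#' Flav are the configured response maps of leaf N; per-leaf values apply
#' the position gradients and position-specific lognormal noise; NBI is
#' computed from the noisy channels.  At tillering the fifth leaf is
#' unavailable and is imputed from leaves 1-4 (flagged).
#'
#' @param config a [trial_config()].
#' @return list with `observations` (a plot-observation data.table, see
#'   [read_dataset()]) and `ground_truth` (per-row true NNI, Nc, PNC, LNC,
#'   the generating curve, and `lin_ctrl_mean`, a non-saturating linear
#'   control channel carrying the same noise, used to calibrate
#'   saturation diagnostics).
#' @export
generate_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  cfg <- config
  des <- cfg$design
  plots <- des[rep(seq_len(nrow(des)), lengths(des$rates))]
  plots[, "n_rate" := unlist(des$rates)]
  plots[, "rates" := NULL]
  plots <- plots[rep(seq_len(nrow(plots)), each = cfg$replicates)]
  plots[, "replicate" := rep(seq_len(cfg$replicates),
                             length.out = nrow(plots))]
  obs <- plots[rep(seq_len(nrow(plots)), each = length(cfg$stages))]
  obs[, "stage" := rep(cfg$stages, length.out = nrow(obs))]
  n <- nrow(obs)

  set.seed(cfg$seed)
  sidx <- match(obs$stage, rice_stages)
  wstage <- cfg$stage_biomass[match(obs$stage, names(cfg$stage_biomass))]
  rmax <- vapply(des$rates, max, numeric(1))
  rmax[rmax == 0] <- 1
  rnorm_rate <- obs$n_rate / rmax[match(obs$variety, des$variety)]

  # Auxiliary (agronomic) noise scales with the sensor noise level so a
  # noise_sd = 0 configuration is a fully deterministic world.
  nz <- cfg$noise_sd / 0.05

  # (i) biomass: stage-driven, mildly increasing in N rate
  w <- wstage * (1 + 0.25 * rnorm_rate) * exp(stats::rnorm(n, 0, 0.08 * nz))

  # (ii) target NNI increasing in N rate, small variety and plot effects
  veff <- stats::rnorm(nrow(des), 0, 0.03 * nz)
  nni <- cfg$nni_range[1] +
    diff(cfg$nni_range) * rnorm_rate^0.8 +
    veff[match(obs$variety, des$variety)] +
    stats::rnorm(n, 0, 0.05 * nz)
  nni <- pmin(pmax(nni, 0.35), 1.45)

  # (iii)-(iv) plant and leaf N from the dilution curve
  nc <- cfg$curve_a * w^(-cfg$curve_b)
  pnc <- nni * nc
  # leaves are richer in N than the whole plant, increasingly so as stem
  # and panicle mass dilutes plant N at later stages
  enrich <- 1.05 + 0.12 * (sidx - 1)
  lnc <- pnc * enrich

  # stage reference leaf N: what a mid-supply (NNI = 0.9) crop would show,
  # used to dilute the signal carried by lower leaves
  w_ref <- cfg$stage_biomass[match(obs$stage, names(cfg$stage_biomass))] *
    (1 + 0.25 * 0.5)
  lnc_ref <- 0.9 * cfg$curve_a * w_ref^(-cfg$curve_b) * enrich
  # per-plot nitrogen-history deviation: lower leaves reflect the plot's
  # accumulated N status (senescence, shading), a deviation shared by all
  # positions of the plot rather than independent sensor noise
  lnc_hist <- lnc_ref * exp(stats::rnorm(n, 0, cfg$leaf_history_sd * nz))

  # per-variety leaf-optics calibration (shared by both channels, hence
  # cancelled by the NBI ratio) and the stage-dependent chlorophyll gain
  vcal <- exp(stats::rnorm(nrow(des), 0, cfg$variety_cal_sd * nz))
  vi <- match(obs$variety, des$variety)
  sgain <- cfg$chl_stage_gain[match(obs$stage, names(cfg$chl_stage_gain))]

  chl <- matrix(NA_real_, n, 5)
  flav <- matrix(NA_real_, n, 5)
  for (p in 1:5) {
    lam <- cfg$leaf_signal_mix[p]
    lnc_eff <- lam * lnc + (1 - lam) * lnc_hist
    nsd <- cfg$noise_sd * cfg$noise_position_scale[p]
    chl[, p] <- chl_response(lnc_eff, cfg$chl_max, cfg$chl_k) *
      sgain * vcal[vi] *
      cfg$leaf_gradient_chl[p] * exp(stats::rnorm(n, 0, nsd))
    flav[, p] <- flav_response(lnc_eff, cfg$flav_intercept, cfg$flav_slope,
                               cfg$flav_floor) *
      vcal[vi] *
      cfg$leaf_gradient_flav[p] * exp(stats::rnorm(n, 0, nsd))
  }

  # (x) at tillering the fifth leaf is not yet expanded: impute from 1-4
  ti <- obs$stage == "TI"
  if (any(ti)) {
    chl[ti, 5] <- rowMeans(chl[ti, 1:4, drop = FALSE])
    flav[ti, 5] <- rowMeans(flav[ti, 1:4, drop = FALSE])
  }
  nbi <- chl / flav                          # (ix) after noise

  pnc_obs <- pnc * exp(stats::rnorm(n, 0, cfg$lab_noise_sd))
  lnc_obs <- lnc * exp(stats::rnorm(n, 0, cfg$lab_noise_sd))

  # linear control channel: same noise law, no saturation by construction
  lin_ctrl <- (10 + 8 * lnc) * exp(stats::rnorm(n, 0, cfg$noise_sd))

  out <- data.table::data.table(
    site = obs$site, variety = obs$variety, subspecies = obs$subspecies,
    n_rate = obs$n_rate, stage = obs$stage,
    biomass_w = w, lnc = lnc_obs, pnc = pnc_obs)
  for (p in 1:5) data.table::set(out, j = paste0("chl_l", p),
                                 value = chl[, p])
  for (p in 1:5) data.table::set(out, j = paste0("flav_l", p),
                                 value = flav[, p])
  for (p in 1:5) data.table::set(out, j = paste0("nbi_l", p),
                                 value = nbi[, p])
  out[, "leaf5_imputed" := as.integer(ti)]

  truth <- data.table::data.table(
    row = seq_len(n), nni_true = nni, nc_true = nc,
    pnc_true = pnc, lnc_true = lnc, lin_ctrl_mean = lin_ctrl,
    curve_a = cfg$curve_a, curve_b = cfg$curve_b)
  list(observations = out[], ground_truth = truth)
}
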