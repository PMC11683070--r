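---
title: "riceNsat: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riceNsat: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Leaf-clip optical sensors (Dualex-type) report a chlorophyll index
(Chl), a flavonoid index (Flav) and their ratio, the Nitrogen Balance
Index (NBI = Chl/Flav), as fast proxies for crop nitrogen status.
Chlorophyll-based readings are known to *saturate*: above a moderate
nitrogen supply, additional nitrogen no longer raises the reading, so
high-nitrogen plots become indistinguishable.  Flavonoids accumulate
under nitrogen shortage and decline roughly linearly as nitrogen status
improves, so Flav (and the composite NBI) keep discriminating where Chl
does not.  `riceNsat` implements, for rice:

1. the critical nitrogen dilution curve and Nitrogen Nutrition Index,
2. an incremental rate-of-change analysis that quantifies sensor
   saturation without fitting any response model,
3. a benchmark of seven regression families for estimating leaf N
   concentration (LNC, % dry mass), plant N concentration (PNC) and NNI
   from multi-leaf sensor readings, and
4. exact interventional Shapley attributions for the tree ensembles,

together with a synthetic field-trial generator that makes the entire
pipeline testable without access to field data.

## Nitrogen indices

The critical N concentration is the power law `Nc = a * W^(-b)` with
above-ground dry matter `W` in t/ha; the package's reference
(published) rice curve is `a = 3.44`, `b = 0.43`, and
`NNI = PNC / Nc` (> 1 surplus, 1 sufficiency, < 1 deficiency).

`fit_dilution_curve()` estimates `(a, b)` from a cloud of `(W, PNC)`
points by a boundary-line construction: observations are binned by
biomass quantiles (default 8 bins, at least 5 points per usable bin,
biomass floor 0.5 t/ha), each bin contributes its minimum-PNC
observation as a boundary point, and the power law is fitted by
ordinary least squares in log–log space (exact for power laws, no
initialisation or step-size choices).  Two design decisions deserve
note:

* **Boundary abscissa.** The boundary point is the minimum-PNC
  observation itself, `(W_argmin, PNC_min)`, not a bin summary such as
  the median `W`.  With a bin-summary abscissa the estimator is biased
  even on noiseless data that lie exactly on a power law (the minimum
  falls at the high-`W` edge of a bin while the summary sits in the
  middle); with the argmin abscissa the noiseless case is recovered
  exactly, which the tests assert to 1e-6.
* **Input scope.** A lower-envelope estimator presumes that crops that
  are *not* nitrogen-limited are present at every biomass level.
  Applied to a whole trial including zero-N plots, the lower envelope
  is the most deficient treatment, not the critical curve.  Parameter
  recovery from the synthetic trial therefore fits on the subset with
  true NNI >= 1; the same subsetting is used by the `curve = "fit"`
  pipeline mode, which filters with the published curve first.

## The incremental saturation analysis

For a sensor variable X and a nitrogen index Y the analysis runs:
min–max scale both to [0, 1]; sort pairs by scaled X (stable sort, ties
keep input order); form adjacent increments ΔX_i, ΔY_i; compute
`rate_i = ΔY_i / ΔX_i` only where `|ΔX_i| >= 1e-3` (NaN otherwise —
tied or near-tied X values would otherwise produce unbounded rates);
normalise by the maximum finite |rate| to [-1, 1]; smooth with a
centred 5-point moving average.  Edge positions use a shrinking window
(no padding values are fabricated), NaN rates are excluded both from
the normalising maximum and from window means, and an all-NaN window
stays NaN.  The scaled-Y denominator is `Ymax - Ymin` (plain min–max
scaling).

The saturation readout has two parts:

* **Top-fraction density.** Samples whose scaled Y lies in the top 20%
  of the scaled range (`y_scaled >= 0.8`) are selected and a Gaussian
  KDE of their scaled X values is evaluated on a 512-point grid over
  [0, 1]; the argmax `peak_x` is the headline statistic.  Selection is
  deliberately by *position in the scaled range*, not by sample
  quantile: under a sample quantile, any monotone noiseless response —
  saturating or not — selects exactly the same rows and the diagnostic
  collapses.  A saturated response leaves many samples near maximal Y
  spread over a wide sensor span, so its density peak falls well below
  1, while a linear response confines them to the top of the sensor
  scale (peak around 0.8–0.9).  Bandwidth is Scott's rule
  (`sd(x) * n^(-1/5)`), overridable by a number; with fewer than two
  distinct X values the single X is returned with a `degenerate` flag.
* **Summary ratio.** The mean |smoothed rate| over the top quartile of
  scaled X divided by the mean over the interquartile range.  A linear
  relation gives 1, a saturating one gives values well below 1 (the
  tests use < 0.5 for `1 - exp(-5x)`).  Absolute values make the
  statistic orientation-free (Flav is negatively related to N).  This
  scalar is a package addition for programmatic comparison; the peak
  location is the primary diagnostic.

## The regression benchmark

Seven families with frozen hyperparameters: single-variable linear (LR)
and quadratic (QCR) baselines on a channel mean; PLS with 2 components;
SVR with RBF kernel, C = 1, epsilon = 0.2, gamma = 1/(p * Var(X)); RF
with 30 trees of depth 5; gradient boosting (XGB) with 30 trees of
depth 4, learning rate 0.1, L1 = L2 = 0.5; and a one-hidden-layer
(100 ReLU units) network trained by minibatch Adam (batch
min(200, n), initial rate 1e-3, adaptive schedule: rate divided by 5
after two stagnant epochs, stop after 10 stagnant epochs or 500
epochs; non-convergence at 500 epochs is logged, not fatal).

Because no R implementations of these learners are assumed, the
package carries its own: a compiled exact-greedy gradient/hessian tree
learner (least-squares CART is the special case g = -y, h = 1; the
boosting tree uses second-order gain with soft-thresholded L1 and L2
leaf regularisation), NIPALS PLS, and an epsilon-SVR solved by cyclic
coordinate descent on the dual with the intercept absorbed into the
kernel (K + 1).  The absorbed intercept is *regularised*, a small,
documented deviation from the equality-constrained dual; it removes
the coupling constraint so each coordinate has a closed-form
soft-threshold update, making the solver deterministic and dependency
free.

Features are standardised (training folds only) for PLS, SVR and the
network; tree models consume raw features.  Evaluation uses 10-fold
cross-validation with seeded random fold assignment: training metrics
are the across-fold mean of in-fold metrics, validation metrics are
computed once on the pooled out-of-fold predictions.  Metrics are
R², RMSE and RRMSE = 100 * RMSE / mean(Y).  LR/QCR are evaluated
in-sample, mirroring their exploratory role.  The NNI target is
computed from PNC, biomass and a dilution curve (published curve by
default).

## Shapley attribution

Attributions for RF and XGB use the interventional value function: the
value of a coalition S is the mean model output over background rows
whose S-features are replaced by the explained sample's values.  For a
tree this is computed exactly by a per-background-row recursion that
partitions leaves by the features forced to the sample's side (A) or
the background row's side (B); a leaf of value v contributes
`+ v (a-1)! b! / (a+b)!` to each feature in A and
`- v a! (b-1)! / (a+b)!` to each in B.  Additivity
(`base_value + sum(phi) = prediction`) holds to machine precision and
is asserted for every sample; a brute-force coalition-enumeration
oracle (p <= 10) verifies the recursion on small models.  The
background is the training data capped at 200 rows by a seeded
subsample; attribution reports use a single full-data refit rather
than the 10 CV models, giving one coherent report.

## The synthetic world

The generator reproduces the factorial structure of a 15-variety,
four-site rice trial (each variety with its own 3–6 step nitrogen-rate
ladder including a zero-N control, 3 replicates, stages TI/SE/PI/HD)
and the following response structure, with every default stated here
rather than tuned per analysis:

* biomass grows near-geometrically with stage (about 1 to 12 t/ha) and
  mildly (up to +25%) with nitrogen rate;
* a target NNI rises with relative nitrogen rate from 0.45 (zero N) to
  about 1.35, clipped to [0.35, 1.45]; PNC = NNI * 3.44 * W^(-0.43);
  LNC is PNC times a leaf-enrichment factor growing from 1.05 (TI) to
  1.41 (HD) as stem and panicle mass dilutes plant N;
* mean Chl is a saturating map of leaf N,
  `42 * (1 - exp(-0.55 * LNC))`, times a stage gain (0.75 at TI rising
  to 1.10 at HD: young thin leaves read lower per-area chlorophyll at
  equal mass-based N); mean Flav is affine-decreasing,
  `2.8 - 0.35 * LNC`, floored at 0.2, with no stage effect;
* a per-variety leaf-optics calibration factor (SD 4%) multiplies both
  channels — and therefore cancels in NBI, which is what makes NBI the
  most genotype-robust index in the generated world;
* leaf positions: multiplicative gradients (+-15%: Chl and NBI highest
  in top leaves, Flav highest in lower leaves); lower leaves track a
  plot-level nitrogen-history baseline (SD 25%) instead of the current
  leaf N (signal weights 1.00 down to 0.55 by position), and
  position-specific sensor noise grows from 0.6x (top) to 1.8x
  (bottom) of the nominal 5% lognormal noise;
* NBI is computed from the noisy channels; at TI the fifth leaf is
  imputed from leaves 1–4 per channel and flagged;
* ground truth additionally carries a *linear control channel*
  (`10 + 8 * LNC` with the same noise law) used to calibrate the
  saturation diagnostics.

Two design points were learned the hard way and are worth recording.
First, a monotone saturating map plus independent 5% noise is *not*
sufficient to make the top-of-range density peak fall below a linear
control's: the compressed within-subset spread and the noise-inflated
scale maximum nearly cancel.  The separation seen in real data comes
from response heterogeneity — here the stage-dependent chlorophyll
gain — which makes high-N early-stage plants overlap moderate-N
late-stage plants on the Chl scale.  With that structure the
saturating channel's peak falls below the linear control's in 200 of
200 test seeds.  Second, with channel means and an imputed fifth leaf
in the feature set, aggregate features legitimately compete with
single top leaves in attribution rankings; the tests therefore assert
the substantive pattern (Flav/NBI channels and top-leaf positions
dominate LNC attribution, chlorophyll never ranks) rather than one
exact top-3 set.

What the generator does **not** emulate: weather, soil and management
variation between sites (sites differ only through their varieties and
rate ladders), spatial correlation among plots, measurement-day
effects, canopy-level reflectance, or real varietal genetics.  A green
test suite therefore establishes that the *methods* behave as designed
on data with the stated structure — not that the package reproduces
the field study's numerical results, which depend on undeposited data.

## Runtime scaling

The acceptance suite's benchmark-ordering criterion runs ten full
cross-validated sweeps; to keep the default test run within its budget
these use a reduced layout (6 of the 15 varieties, one replicate,
about 104 observations per trial).  The orderings it asserts (LNC
easier than NNI for every family; the Chl-only combination worst for
LNC) also hold at the full default size, as the development record in
the repository notes.

## Known limitations

* The SVR intercept is regularised (kernel-absorbed), so coefficients
  differ slightly from solvers honouring the exact dual constraint.
* The network is a faithful but minimal Adam MLP; convergence at 500
  epochs is not guaranteed and is reported via messages.
* `fit_dilution_curve()` requires non-N-limited input to estimate the
  *critical* curve; it will happily fit the lower envelope of whatever
  it is given.
* Saturation diagnostics are descriptive: `peak_x` has no attached
  significance test, by design (the method deliberately avoids model
  fitting).
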