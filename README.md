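# riceNsat

Saturation-aware nitrogen status diagnostics for rice from leaf-clip
optical sensor readings.

## What it is for

Agronomists and crop-phenotyping researchers estimate rice nitrogen
status from Dualex-type leaf-clip readings — a chlorophyll index
(Chl), a flavonoid index (Flav) and the Nitrogen Balance Index
(NBI = Chl/Flav) — taken on the top five leaves (LFT 1–5).
Chlorophyll readings *saturate* at high nitrogen supply and stop
discriminating exactly where fertiliser decisions matter most; Flav
and NBI keep responding.  `riceNsat` provides the full analysis chain
for quantifying that saturation and for benchmarking nitrogen
estimation models:

* **Nitrogen indices** — critical N dilution curve `Nc = a·W^(−b)`
  (reference rice curve `3.44·W^(−0.43)`), boundary-line fitting from
  `(W, PNC)` clouds, and the Nitrogen Nutrition Index
  `NNI = PNC/Nc` (>1 surplus, 1 sufficiency, <1 deficiency).
* **Saturation analysis** — a model-free incremental procedure:
  min–max scale X (sensor) and Y (nitrogen index), sort by X, form
  adjacent rates ΔY/ΔX (|ΔX| ≥ 10⁻³), normalise to [−1, 1], smooth
  with a 5-point moving average, and locate the Gaussian-KDE density
  peak of X among the samples in the top 20% of the scaled Y range.
  A peak well below 1 means the sensor no longer separates the
  best-nourished plants: saturation.
* **Regression benchmark** — seven families (LR, QCR, PLS, SVR, RF,
  XGB, NN) with fixed hyperparameters, four input combinations
  (6 Chl / 6 Flav / 6 NBI columns, or all 18), targets LNC, PNC and
  NNI, under seeded 10-fold cross-validation with R², RMSE and RRMSE.
  All learners are implemented natively (compiled exact-greedy trees
  for RF/XGB; NIPALS PLS; coordinate-descent ε-SVR; Adam MLP).
* **Attribution** — exact interventional Shapley values for the tree
  ensembles (verified against a brute-force coalition oracle), with
  mean-|SHAP| feature rankings.
* **Synthetic trials** — a generator reproducing the structure of a
  15-variety, 4-site nitrogen-rate experiment with known ground truth
  (true NNI, the generating curve, and a linear control channel), so
  every stage is testable without field data.

See `vignettes/riceNsat-methods.Rmd` for the model, all tunable
parameters and the design decisions.

## Worked example

```r
library(riceNsat)

tr  <- generate_trial(trial_config(seed = 1))   # 792 plot observations
obs <- tr$observations
ft  <- feature_table(obs)                       # the 18 input variables

# saturation of the three channel means against leaf N concentration
run_saturation_analysis(ft$Chl_mean,  obs$lnc)
#> Saturation trace: n = 792, density peak at x = 0.650, summary ratio = 0.518
run_saturation_analysis(ft$Flav_mean, obs$lnc)
#> Saturation trace: n = 792, density peak at x = 0.162, summary ratio = 0.823
run_saturation_analysis(ft$NBI_mean,  obs$lnc)
#> Saturation trace: n = 792, density peak at x = 0.724, summary ratio = 0.188
```

The best-nourished plants sit at only 0.65 of the chlorophyll scale —
Chl readings overlap with moderate-nitrogen plots (saturation) — while
on the NBI scale they sit higher (0.72) and on the flavonoid scale
they form the expected low-Flav cluster (0.16; Flav falls as nitrogen
rises).

```r
# dilution curve from the non-N-limited subset, and a benchmark cell
sub <- tr$ground_truth$nni_true >= 1
fit_dilution_curve(obs$biomass_w[sub], obs$pnc[sub])
#> Critical N dilution curve: Nc = 3.36 * W^(-0.4097)  [8 boundary points]

cv <- cross_validate(model_config("RF", 1),
                     build_feature_combinations(ft)$All, obs$lnc)
cv$validation_metrics
#> $r2 0.973; $rmse 0.168; $rrmse 7.2   (pooled out-of-fold)
```

The fitted curve recovers the generating parameters (3.44, 0.43)
within a few percent; a 30-tree random forest on all 18 variables
estimates LNC with out-of-fold R² ≈ 0.97 on this synthetic world
(cleaner than any field data — see the vignette for what that does
and does not establish).

Full pipeline and CLI:

```r
run_all(list(mode = "simulate", seed = 1), out_dir = "run1")
```

```sh
inst/cli/ricensat simulate  --config cfg.json --out run1
inst/cli/ricensat nni       --dataset run1/dataset.csv --out run1
inst/cli/ricensat benchmark --dataset run1/dataset.csv --out run1
```

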