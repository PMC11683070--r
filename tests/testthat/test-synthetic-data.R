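test_that("generation is deterministic in the seed and varies across seeds", {
  t1 <- generate_trial(small_trial_config(5))
  t2 <- generate_trial(small_trial_config(5))
  t3 <- generate_trial(small_trial_config(6))
  expect_identical(t1$observations, t2$observations)
  expect_identical(t1$ground_truth, t2$ground_truth)
  expect_false(isTRUE(all.equal(t1$observations$lnc, t3$observations$lnc)))
  # byte-identical CSVs
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(t1$observations, f1)
  write_dataset(t2$observations, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("noise-free single-plot world reproduces the dilution identity", {
  d <- data.table::data.table(variety = "V1", subspecies = "japonica",
                              site = "S1", rates = list(0))
  cfg <- trial_config(design = d, stages = "SE", replicates = 1L, seed = 1,
                      noise_sd = 0, lab_noise_sd = 0, nni_range = c(1, 1),
                      stage_biomass = c(TI = 1, SE = 1, PI = 1, HD = 1,
                                        GF = 1))
  tr <- generate_trial(cfg)
  # NNI = 1 and W = 1 force PNC = a
  expect_equal(tr$observations$biomass_w, 1)
  expect_equal(tr$observations$pnc, 3.44, tolerance = 1e-12)
})

test_that("pre-noise ground truth satisfies NNI = PNC / (a W^-b) exactly", {
  tr <- generate_trial(small_trial_config(2))
  gt <- tr$ground_truth
  expect_equal(gt$pnc_true / gt$nc_true, gt$nni_true, tolerance = 1e-12)
  expect_equal(gt$nc_true,
               gt$curve_a * tr$observations$biomass_w^(-gt$curve_b),
               tolerance = 1e-12)
})

test_that("response maps are monotone with chlorophyll saturating", {
  lnc <- seq(0.5, 5, by = 0.01)
  chl <- chl_response(lnc)
  expect_true(all(diff(chl) > 0))
  expect_true(all(chl < 42))
  # derivative at the 90th percentile is smaller than at the median
  d <- function(x, eps = 1e-4) (chl_response(x + eps) - chl_response(x)) / eps
  expect_lt(d(quantile(lnc, 0.9)), d(quantile(lnc, 0.5)))
  flav <- flav_response(seq(0.1, 9, by = 0.01))
  expect_true(all(diff(flav) < 0))
  expect_true(all(flav > 0))
})

test_that("generated world shows the designed saturation structure", {
  tr <- generate_trial(trial_config(seed = 2000))
  obs <- tr$observations
  ft <- feature_table(obs)
  expect_gt(nrow(obs), 500)
  # flavonoids decrease with leaf N over the whole range
  expect_lt(cor(ft$Flav_mean, obs$lnc), -0.8)
  # chlorophyll-LNC coupling degrades in the top LNC quartile
  qs <- quantile(obs$lnc, c(0.25, 0.75))
  top <- obs$lnc >= qs[2]; bot <- obs$lnc <= qs[1]
  expect_lt(cor(ft$Chl_mean[top], obs$lnc[top]),
            cor(ft$Chl_mean[bot], obs$lnc[bot]))
  # NNI within the reported field range
  expect_gte(min(tr$ground_truth$nni_true), 0.3)
  expect_lte(max(tr$ground_truth$nni_true), 1.5)
})

test_that("tillering rows have the fifth leaf imputed per channel", {
  tr <- generate_trial(small_trial_config(3))
  obs <- tr$observations
  ti <- obs$stage == "TI"
  expect_true(all(obs$leaf5_imputed[ti] == 1L))
  expect_true(all(obs$leaf5_imputed[!ti] == 0L))
  chl14 <- rowMeans(as.matrix(
    obs[ti, paste0("chl_l", 1:4), with = FALSE]))
  flav14 <- rowMeans(as.matrix(
    obs[ti, paste0("flav_l", 1:4), with = FALSE]))
  expect_equal(obs$chl_l5[ti], chl14, tolerance = 1e-12)
  expect_equal(obs$flav_l5[ti], flav14, tolerance = 1e-12)
  # NBI recomputed from the imputed channels, not averaged directly
  expect_equal(obs$nbi_l5[ti], chl14 / flav14, tolerance = 1e-12)
})

test_that("degenerate configurations are rejected", {
  expect_error(trial_config(design = NULL), "config error")
  expect_error(trial_config(stages = character(0)), "must be one of|config")
  expect_error(trial_config(replicates = 0), "config error")
  expect_error(trial_config(curve_b = 1.2), "config error")
  expect_error(trial_config(noise_sd = -0.1), "config error")
})
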