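test_that("attributions are additive and match the brute-force oracle", {
  set.seed(31)
  x <- matrix(rnorm(90), 30, 3)
  colnames(x) <- c("a", "b", "c")
  y <- 2 * x[, 1] + 1.5 * (x[, 2] > 0) + rnorm(30, 0, 0.1)
  bg <- x[1:8, ]
  for (fam in c("RF", "XGB")) {
    fit <- fit_model(model_config(fam, 2), x, y)
    rep_ <- attribute(fit, x, bg)
    pred <- predict(fit, x)
    expect_equal(rep_$base_value + rowSums(rep_$values), pred,
                 tolerance = 1e-9, label = paste(fam, "additivity"))
    pf <- function(m) predict(fit, m)
    for (i in c(1, 7, 30))
      expect_equal(rep_$values[i, ], shapley_oracle(pf, x[i, ], bg),
                   tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("a constant model attributes nothing", {
  x <- matrix(rnorm(60), 20, 3)
  colnames(x) <- paste0("f", 1:3)
  fit <- fit_model(model_config("RF", 1), x, rep(2.5, 20))
  rep_ <- attribute(fit, x, x)
  expect_equal(unname(rep_$values), matrix(0, 20, 3))
  expect_equal(rep_$base_value, 2.5)
  # ties: ranking falls back to column order
  rk <- rank_features(rep_)
  expect_identical(rk$feature, paste0("f", 1:3))
})

test_that("features the trees never split on get exactly zero", {
  set.seed(32)
  x <- cbind(sig = rnorm(40), dead1 = rep(1, 40), dead2 = rep(0, 40))
  y <- 3 * x[, 1] + rnorm(40, 0, 0.1)
  for (fam in c("RF", "XGB")) {
    fit <- fit_model(model_config(fam, 3), x, y)
    rep_ <- attribute(fit, x, x)
    expect_true(all(rep_$values[, c("dead1", "dead2")] == 0))
    expect_gt(mean(abs(rep_$values[, "sig"])), 0)
    expect_identical(rank_features(rep_)$feature[1], "sig")
  }
})

test_that("the oracle satisfies the additive closed form and symmetry", {
  set.seed(33)
  bg <- matrix(rnorm(50 * 3), 50, 3)
  g1 <- function(v) 2 * v
  g2 <- function(v) v^2
  g3 <- function(v) sin(v)
  f <- function(m) g1(m[, 1]) + g2(m[, 2]) + g3(m[, 3])
  s <- c(0.4, -1.2, 2)
  phi <- shapley_oracle(f, s, bg)
  expect_equal(phi, c(g1(s[1]) - mean(g1(bg[, 1])),
                      g2(s[2]) - mean(g2(bg[, 2])),
                      g3(s[3]) - mean(g3(bg[, 3]))), tolerance = 1e-12)
  # symmetry: interchangeable features with equal sample values
  fsym <- function(m) m[, 1] * m[, 2] + m[, 1] + m[, 2]
  bg2 <- cbind(bg[, 1], bg[, 1])
  phi2 <- shapley_oracle(fsym, c(0.8, 0.8), bg2)
  expect_equal(phi2[1], phi2[2], tolerance = 1e-12)
  expect_error(shapley_oracle(f, rnorm(11), matrix(rnorm(22), 2, 11)),
               "refusing")
})

test_that("attribution refuses unsupported models and empty backgrounds", {
  x <- matrix(rnorm(60), 20, 3); colnames(x) <- paste0("f", 1:3)
  y <- rnorm(20)
  pls <- fit_model(model_config("PLS", 1), x, y)
  expect_error(attribute(pls, x, x), "state error")
  rf <- fit_model(model_config("RF", 1), x, y)
  expect_error(attribute(rf, x, x[0, , drop = FALSE]), "empty background")
})

test_that("top-leaf Flav/NBI features dominate LNC attribution", {
  # the generated world places the cleanest nitrogen signal in the top
  # leaves and cancels genotype calibration in the NBI ratio; chlorophyll
  # saturates.  The ranking must reflect that: Flav_L1 at the top, the
  # leading features drawn from the Flav/NBI channels, and no Chl
  # feature among them.
  leader_sets <- list()
  for (s in 1:3) {
    tr <- generate_trial(trial_config(seed = s))
    obs <- tr$observations
    ft <- as.matrix(feature_table(obs))
    fit <- fit_model(model_config("RF", s), ft, obs$lnc)
    rep_ <- attribute(fit, ft[seq(1, nrow(ft), by = 4), ], ft, seed = s)
    top5 <- rep_$ranking[1:5]
    expect_true("Flav_L1" %in% rep_$ranking[1:2])
    expect_false(any(grepl("^Chl", top5)))
    expect_true(all(grepl("^(Flav|NBI)", top5)))
    leader_sets[[s]] <- top5
  }
  # the dominant predictors come from the top two leaf positions or the
  # channel aggregates, never from raw deep-leaf chlorophyll
  pool <- unlist(leader_sets)
  expect_gt(mean(pool %in% c("Flav_L1", "Flav_L2", "NBI_L1", "NBI_L2",
                             "NBI_mean", "Flav_mean", "NBI_L5", "Flav_L5")),
            0.8)
})
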