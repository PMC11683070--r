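test_that("metrics match their definitions and a naive loop oracle", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(rmse(c(2, 4), c(3, 3)), 1)
  expect_equal(rrmse(c(2, 4), c(3, 3)), 100 / 3)
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(50, 5); p <- a + rnorm(50, 0, 0.7)
    ref <- naive_metrics(a, p)
    expect_equal(r_squared(a, p), ref$r2, tolerance = 1e-12)
    expect_equal(rmse(a, p), ref$rmse, tolerance = 1e-12)
    expect_equal(rrmse(a, p), ref$rrmse, tolerance = 1e-12)
  }
  expect_error(r_squared(rep(1, 5), rnorm(5)), "zero-variance")
  expect_error(rrmse(c(-1, 1), c(0, 0)), "zero-mean")
})

test_that("metric scaling identities hold", {
  set.seed(22)
  a <- rnorm(40, 10); p <- a + rnorm(40)
  for (cc in c(0.3, 2, -1.5))
    expect_equal(rmse(cc * a, cc * p), abs(cc) * rmse(a, p),
                 tolerance = 1e-12)
  for (cc in c(0.3, 2))
    expect_equal(rrmse(cc * a, cc * p), rrmse(a, p), tolerance = 1e-12)
})

test_that("simple regressions recover exact generating polynomials", {
  x <- seq(0, 2, by = 0.1)
  lr <- fit_simple_regression(x, 2 * x + 1, "LR")
  expect_equal(lr$coefficients, c(1, 2), tolerance = 1e-9)
  expect_equal(lr$metrics$r2, 1, tolerance = 1e-12)
  q <- fit_simple_regression(x, x^2, "QCR")
  expect_equal(q$metrics$r2, 1, tolerance = 1e-12)
  lr2 <- fit_simple_regression(x, x^2, "LR")
  expect_lt(lr2$metrics$r2, 1)
  expect_error(fit_simple_regression(rep(1, 10), rnorm(10), "LR"),
               "constant predictor")
})

test_that("fold assignment is a seeded balanced partition", {
  f <- make_folds(103, 10, seed = 4)
  expect_length(f, 103)
  expect_setequal(unique(f), 1:10)
  sizes <- sort(as.integer(table(f)))
  expect_identical(sizes, sort(c(rep(10L, 7), rep(11L, 3))))
  expect_identical(f, make_folds(103, 10, seed = 4))
  expect_false(identical(f, make_folds(103, 10, seed = 5)))
  expect_error(make_folds(5, 10), "insufficient data")
})

test_that("cross-validation is deterministic and partitions rows", {
  set.seed(23)
  x <- matrix(rnorm(600), 120, 5)
  colnames(x) <- paste0("f", 1:5)
  y <- x %*% c(1, -2, 0.5, 0, 0) + rnorm(120, 0, 0.3)
  cv1 <- cross_validate(model_config("RF", 1), x, y, k = 10, seed = 9)
  cv2 <- cross_validate(model_config("RF", 1), x, y, k = 10, seed = 9)
  expect_identical(cv1$fold_assignments, cv2$fold_assignments)
  expect_identical(cv1$oof_predictions, cv2$oof_predictions)
  expect_identical(cv1$validation_metrics, cv2$validation_metrics)
  expect_false(any(is.na(cv1$oof_predictions)))
  expect_error(cross_validate(model_config("RF"), x * NA, y),
               "validation error")
})

test_that("every family learns a smooth signal reasonably", {
  set.seed(24)
  n <- 150
  x <- matrix(runif(n * 4), n, 4)
  colnames(x) <- paste0("f", 1:4)
  y <- drop(3 * x[, 1] - 2 * x[, 2]^2 + 0.5 * x[, 3]) + rnorm(n, 0, 0.05)
  for (fam in c("PLS", "SVR", "RF", "XGB", "NN")) {
    fit <- suppressMessages(fit_model(model_config(fam, 3), x, y))
    r2 <- r_squared(y, predict(fit, x))
    expect_gt(r2, 0.75, label = paste(fam, "in-sample r2"))
  }
})

test_that("hyperparameters are frozen per family", {
  cfg <- model_config("XGB")
  expect_equal(cfg$hyper$n_estimators, 30L)
  expect_equal(cfg$hyper$max_depth, 4L)
  expect_equal(cfg$hyper$learning_rate, 0.1)
  expect_equal(cfg$hyper$reg_alpha, 0.5)
  expect_equal(cfg$hyper$reg_lambda, 0.5)
  expect_equal(model_config("RF")$hyper,
               list(n_estimators = 30L, max_depth = 5L))
  expect_equal(model_config("PLS")$hyper$n_components, 2L)
  expect_equal(model_config("SVR")$hyper$C, 1.0)
  expect_equal(model_config("SVR")$hyper$epsilon, 0.2)
  expect_equal(model_config("NN")$hyper$hidden, 100L)
  expect_equal(model_config("NN")$hyper$max_iter, 500L)
  expect_error(model_config("GBM"), "arg")
  # LR accepts exactly one column
  x2 <- matrix(rnorm(40), 20, 2)
  expect_error(fit_model(model_config("LR"), x2, rnorm(20)),
               "one input column")
})

test_that("benchmark sweep emits the full factorial of cells", {
  obs <- generate_trial(small_trial_config(12))$observations
  b <- run_benchmark(obs, targets = c("LNC", "NNI"),
                     combos = c("Chl", "All"), models = c("PLS", "RF"),
                     k = 5L, seed = 2)
  r <- b$results
  cvcells <- r[r$model %in% c("PLS", "RF"), ]
  expect_equal(nrow(cvcells), 2 * 2 * 2 * 2)   # target x combo x model x split
  expect_setequal(unique(r$split), c("train", "validation", "in_sample"))
  # LR/QCR baselines: 3 channels x 2 families per target
  expect_equal(sum(r$model %in% c("LR", "QCR")), 2 * 3 * 2)
  expect_true(all(is.finite(r$r2)))
})

test_that("extra target noise does not improve validation accuracy", {
  r2_at <- function(noise, seed) {
    tr <- generate_trial(small_trial_config(seed, noise_sd = noise))
    obs <- tr$observations
    ft <- build_feature_combinations(feature_table(obs))$All
    cross_validate(model_config("RF", seed), ft, obs$lnc, k = 5,
                   seed = seed)$validation_metrics$r2
  }
  lo <- median(sapply(31:33, r2_at, noise = 0.05))
  hi <- median(sapply(31:33, r2_at, noise = 0.20))
  expect_lte(hi, lo + 0.02)
})
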