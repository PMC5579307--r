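test_that("PLS1 is exact on noise-free two-component mixtures", {
  rs <- rank2_calset()
  # centred two-component spectra have rank 1: NIPALS stops early
  model <- suppressWarnings(fit_pls1(rs$cal, 2))
  preds <- vapply(seq_along(rs$xs), function(i)
    predict_composition(model, ir_spectrum(rs$grid, rs$cal$X[i, ])),
    numeric(1))
  expect_lt(max(abs(preds - 100 * rs$xs)), 1e-8)   # mol%
})

test_that("zero components predicts the training mean; the mean spectrum maps to it", {
  rs <- rank2_calset(n = 10)
  m0 <- fit_pls1(rs$cal, 0)
  s <- ir_spectrum(rs$grid, rs$cal$X[3, ])
  expect_equal(as.numeric(predict_composition(m0, s, n_components = 0)),
               100 * mean(rs$xs), tolerance = 1e-10)
  m2 <- suppressWarnings(fit_pls1(rs$cal, 2))
  mean_spec <- ir_spectrum(rs$grid, colMeans(rs$cal$X))
  expect_equal(as.numeric(predict_composition(m2, mean_spec)),
               100 * mean(rs$xs), tolerance = 1e-8)
})

test_that("full-component PLS1 matches the least-squares oracle", {
  set.seed(5)
  n <- 8; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  y <- runif(n)
  grid <- seq(1000, 1000 + 2 * (p - 1), 2)
  cal <- calibration_set(y, lapply(seq_len(n), function(i)
    ir_spectrum(grid, X[i, ])))
  model <- fit_pls1(cal, n - 1)
  preds <- vapply(seq_len(n), function(i)
    predict_composition(model, ir_spectrum(grid, X[i, ])) / 100, numeric(1))
  # oracle: minimum-norm least squares on the centred data
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  sv <- svd(Xc)
  keep <- sv$d > 1e-10 * sv$d[1]
  beta <- sv$v[, keep] %*% ((1 / sv$d[keep]) * crossprod(sv$u[, keep], yc))
  oracle <- drop(Xc %*% beta) + mean(y)
  expect_lt(max(abs(preds - oracle)), 1e-8)
})

test_that("PLS1 agrees with an independent implementation on random instances", {
  requireNamespace("mixOmics", quietly = TRUE)
  set.seed(17)
  for (rep in 1:3) {
    n <- 10; p <- 25; k <- 3
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("wn", seq_len(p))))
    y <- rnorm(n)
    fit <- azeoblend:::nipals_pls1(X, y, k)
    preds <- drop(sweep(X, 2, fit$x_mean) %*% fit$coefs[, k]) + fit$y_mean
    mo <- mixOmics::pls(X, y, ncomp = k, scale = FALSE, mode = "regression")
    mo_pred <- predict(mo, X)$predict[, 1, k]
    expect_equal(unname(preds), unname(mo_pred), tolerance = 1e-6)
  }
})

test_that("training RMSE is non-increasing in the number of components", {
  set.seed(23)
  n <- 12; p <- 60
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  fit <- azeoblend:::nipals_pls1(X, y, n - 1)
  rmse <- vapply(seq_len(fit$n_components), function(k) {
    pr <- drop(sweep(X, 2, fit$x_mean) %*% fit$coefs[, k]) + fit$y_mean
    sqrt(mean((pr - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("predictions are invariant to a constant offset on all training spectra", {
  rs <- rank2_calset(n = 12)
  shifted <- calibration_set(rs$xs, lapply(seq_along(rs$xs), function(i)
    ir_spectrum(rs$grid, rs$cal$X[i, ] + 0.25)))
  m1 <- suppressWarnings(fit_pls1(rs$cal, 2))
  m2 <- suppressWarnings(fit_pls1(shifted, 2))
  s1 <- ir_spectrum(rs$grid, rs$cal$X[5, ])
  s2 <- ir_spectrum(rs$grid, rs$cal$X[5, ] + 0.25)
  expect_equal(as.numeric(predict_composition(m1, s1)),
               as.numeric(predict_composition(m2, s2)), tolerance = 1e-8)
})

test_that("LOO cross-validation selects a parsimonious model on exact data", {
  rs <- rank2_calset()
  cv <- loo_cv_select(rs$cal, max_components = 6)
  expect_lte(cv$chosen, 2)
  expect_lt(cv$table$mean_abs_error_molpct[cv$chosen], 1e-6)
  expect_identical(nrow(cv$table), 6L)
})

test_that("LOO report on the 24-mixture synthetic set has 15 rows and is seed-stable", {
  cfg <- generator_config(seed = 7)
  cs <- gen_calibration_set(cfg)
  cv1 <- loo_cv_select(cs$cal, max_components = 15)
  expect_identical(nrow(cv1$table), 15L)
  expect_true(all(is.finite(cv1$table$mean_abs_error_molpct)))
  # noise beats the 1-direction model
  expect_lt(cv1$table$mean_abs_error_molpct[cv1$chosen],
            cv1$table$mean_abs_error_molpct[1])
  # regenerate with the same seed: identical selection
  cv2 <- loo_cv_select(gen_calibration_set(generator_config(seed = 7))$cal, 15)
  expect_identical(cv1$chosen, cv2$chosen)
  expect_equal(cv1$table, cv2$table)
})

test_that("an unknown mixture is predicted within the cross-validated error", {
  cfg <- generator_config(seed = 7)
  cs <- gen_calibration_set(cfg)
  cv <- loo_cv_select(cs$cal, max_components = 15)
  model <- fit_pls1(cs$cal, cv$chosen)
  unknown <- gen_mixture_spectrum(0.30, noise_sd = cfg$spectral_sd, seed = 4242)
  pred <- predict_composition(model, unknown)
  expect_lt(abs(pred - 30),
            max(3 * cv$table$mean_abs_error_molpct[cv$chosen], 0.5))
})

test_that("error metrics summarise absolute differences", {
  expect_equal(error_metrics(c(1, 2), c(1, 2)), c(max_abs = 0, mean_abs = 0))
  expect_equal(error_metrics(c(10, 20), c(12, 20)),
               c(max_abs = 2, mean_abs = 1))
  expect_error(error_metrics(1:3, 1:2), "equal length")
  # max >= mean always on LOO predictions
  cs <- gen_calibration_set(generator_config(seed = 3))
  cv <- loo_cv_select(cs$cal, 5)
  em <- error_metrics(cv$loo_predictions_molpct, cv$truth_molpct)
  expect_gte(em[["max_abs"]], em[["mean_abs"]])
})

test_that("degenerate deflation stops early with a warning", {
  grid <- seq(1000, 1018, 2)
  X <- matrix(rep(seq(0, 1, length.out = 6), 10), 6, 10)  # rank 1 exactly
  cal <- calibration_set(seq(0, 1, length.out = 6),
                         lapply(1:6, function(i) ir_spectrum(grid, X[i, ])))
  expect_warning(m <- fit_pls1(cal, 4), "degenerate")
  expect_lt(m$n_components, 4)
})
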