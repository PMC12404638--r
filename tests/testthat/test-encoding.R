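test_that("lag windows round half-up from window x rate", {
  expect_equal(lag_spec(0.25, 20)$n_lags, 5L)
  expect_equal(lag_spec(0.25, 50)$n_lags, 13L)    # 12.5 rounds up
  expect_equal(lag_spec(0.05, 20)$n_lags, 1L)
  expect_error(lag_spec(0.001, 20), "zero lags")
})

test_that("lagged designs stack past frames and respect stimulus boundaries", {
  fm <- feature_matrix(c(1, 2, 3), 20)
  d <- build_lagged_design(fm, lag_spec(0.1, 20))   # 2 lags
  expect_equal(unname(d), rbind(c(0, 1), c(1, 2), c(2, 3)))

  # n_lags = 1: the design is the feature matrix itself
  d1 <- build_lagged_design(fm, lag_spec(0.05, 20))
  expect_equal(unname(d1), matrix(c(1, 2, 3), 3, 1))

  # list input: lags never cross the stimulus boundary
  fms <- list(a = feature_matrix(c(1, 2), 20), b = feature_matrix(c(5, 6), 20))
  d2 <- build_lagged_design(fms, lag_spec(0.1, 20))
  expect_equal(unname(d2[3, ]), c(0, 5))            # onset of b zero-padded

  expect_error(build_lagged_design(feature_matrix(1:4, 50),
                                   lag_spec(0.1, 20)), "rate")
})

test_that("cross-validated ridge matches the closed-form oracle", {
  grid <- 10^seq(-5, 15, length.out = 21)
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    n <- sample(12:20, 1); p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- X %*% rnorm(p) + rnorm(n, sd = 0.3)
    fit <- fit_trf(X, y, lambda_grid = grid, k_folds = 3,
                   standardize = FALSE)
    oracle <- ridge_oracle(X, y, fit$lambda)
    rel <- sqrt(sum((fit$weights - oracle$weights)^2)) /
      max(sqrt(sum(oracle$weights^2)), 1e-12)
    worst <- max(worst, rel,
                 abs(fit$intercept - oracle$intercept) /
                   max(abs(oracle$intercept), 1))
  }
  expect_lt(worst, 1e-6)
})

test_that("extreme penalties shrink weights far below least squares", {
  set.seed(7)
  X <- matrix(rnorm(120), 40, 3)
  y <- X %*% c(1, -2, 0.5) + rnorm(40, sd = 0.1)
  ls_w <- ridge_oracle(X, y, 0)$weights
  fit <- fit_trf(X, y, lambda_grid = 1e15 * c(1, 1.0001), k_folds = 2,
                 standardize = FALSE)
  expect_lt(sqrt(sum(fit$weights^2)), 1e-6 * sqrt(sum(ls_w^2)))
})

test_that("noiseless linear targets are recovered with held-out correlation near 1", {
  set.seed(11)
  fm <- feature_matrix(matrix(rnorm(240), 120, 2), 20)
  spec <- lag_spec(0.25, 20)
  X <- build_lagged_design(fm, spec)
  w_true <- rnorm(ncol(X))
  y <- as.numeric(X %*% w_true) + 2
  fit <- fit_trf(X[1:90, ], y[1:90])
  pred <- predict(fit, X[91:120, ])
  expect_gt(cor(pred, y[91:120]), 0.999)
  expect_true(fit$lambda <= 1e-2)   # CV picks a light penalty
})

test_that("prediction handles intercept-only and mismatched models", {
  m <- encodetrf:::new_trf_model(weights = c(0, 0), intercept = 1.5,
                                 lambda = 1, cv_curve = NULL,
                                 lambda_grid = 1, k_folds = 3,
                                 degenerate = FALSE, seed = 1)
  expect_equal(predict(m, matrix(rnorm(10), 5, 2)), rep(1.5, 5))
  expect_error(predict(m, matrix(rnorm(9), 3, 3)), "columns")

  # degenerate (all-zero) designs come back flagged with zero weights
  fit0 <- fit_trf(matrix(0, 12, 2), rnorm(12))
  expect_true(fit0$degenerate)
  expect_equal(fit0$weights, c(0, 0))
})

test_that("the multi-unit fitting core agrees with the single-unit path", {
  set.seed(13)
  X <- matrix(rnorm(200), 50, 4)
  Y <- cbind(X %*% rnorm(4) + rnorm(50, sd = 0.2),
             X %*% rnorm(4) + rnorm(50, sd = 0.2))
  multi <- encodetrf:::fit_trf_multi(X, Y)
  for (j in 1:2) {
    single <- fit_trf(X, Y[, j])
    expect_equal(multi$weights[, j], unname(single$weights),
                 tolerance = 1e-10)
    expect_equal(multi$lambda[j], single$lambda)
  }
})

test_that("cv metadata is complete and fold assignment is contiguous", {
  set.seed(17)
  X <- matrix(rnorm(90), 30, 3)
  y <- rnorm(30)
  fit <- fit_trf(X, y)
  expect_equal(nrow(fit$cv_curve), 21)
  expect_true(all(is.finite(fit$cv_curve$mean_mse)))
  expect_true(fit$lambda %in% fit$cv_curve$lambda)
  expect_equal(fit$cv_curve$mean_mse[fit$cv_curve$lambda == fit$lambda],
               min(fit$cv_curve$mean_mse))
  folds <- encodetrf:::contiguous_folds(10, 3)
  expect_equal(folds, c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3))

  g <- glance(fit)
  expect_equal(g$lambda, fit$lambda)
  expect_equal(nrow(tidy(fit)), ncol(X))
})
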