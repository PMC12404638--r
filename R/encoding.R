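#' Lag specification for a temporal receptive field
#'
#' A TRF predicts the response at bin `t` from the features at bins
#' `t - n_lags + 1 ... t`: a causal window. The number of lags is the
#' window length times the rate, rounded half-up (250 ms gives 5 lags at
#' 20 Hz and 13 at 50 Hz).
#'
#' @param window Window length in seconds (default 0.25).
#' @param rate Feature/bin rate in Hz.
#' @return List with `window`, `rate`, `n_lags`.
#' @export
lag_spec <- function(window = 0.25, rate) {
  stopifnot(window > 0, rate > 0)
  n_lags <- as.integer(round_half_up(window * rate))
  if (n_lags < 1) abort("window too short for the rate: zero lags")
  list(window = window, rate = rate, n_lags = n_lags)
}

# design for a single continuous segment: row t = features at
# t-n_lags+1 ... t concatenated oldest-first, zero-padded before onset
lag_design_matrix <- function(x, n_lags) {
  blocks <- lapply(rev(seq_len(n_lags)) - 1L, function(s) shift_down(x, s))
  do.call(cbind, blocks)
}

#' Build a lagged design matrix
#'
#' Stacks, for each time bin, the `n_lags` most recent feature frames
#' (oldest first), zero-padding before each stimulus onset so lags never
#' cross stimulus boundaries.
#'
#' @param fm A `feature_matrix`, or a named list of them (one per
#'   stimulus); list elements are lagged independently and row-bound.
#' @param spec A [lag_spec()]; its `rate` must match the features.
#' @return Numeric matrix with `sum(nrow)` rows and
#'   `ncol(fm) * n_lags` columns.
#' @examples
#' fm <- feature_matrix(c(1, 2, 3), 20)
#' build_lagged_design(fm, lag_spec(0.1, 20))  # rows (0,1) (1,2) (2,3)
#' @export
build_lagged_design <- function(fm, spec) {
  if (inherits(fm, "feature_matrix")) fm <- list(fm)
  stopifnot(length(fm) >= 1)
  mats <- lapply(fm, function(f) {
    stopifnot(inherits(f, "feature_matrix"))
    if (!isTRUE(all.equal(sampling_rate(f), spec$rate))) {
      abort("feature sampling rate does not match the lag spec rate")
    }
    lag_design_matrix(fm_values(f), spec$n_lags)
  })
  do.call(rbind, mats)
}

default_lambda_grid <- function(n = 21L) 10^seq(-5, 15, length.out = n)

#' Fit a temporal receptive field by cross-validated ridge regression
#'
#' Minimizes L2-penalized squared error between the lagged design and the
#' binned spike counts. The penalty is chosen by k-fold cross-validation
#' over a log-spaced grid spanning 1e-5 to 1e15 (21 points by default):
#' folds are contiguous temporal blocks (shuffling bins would leak
#' autocorrelated structure across folds), the ridge solution is computed
#' on the training folds via SVD for all grid points at once, validation
#' mean squared error picks the winner, and the final weights are refit on
#' all data at that penalty. Features are standardized per column on the
#' training data and the intercept is never penalized; returned weights
#' are on the original feature scale.
#'
#' @param design Numeric matrix (bins x lagged features), e.g. from
#'   [build_lagged_design()].
#' @param counts Numeric response vector, one value per design row.
#' @param lambda_grid Penalty grid (default 21 log-spaced points,
#'   1e-5..1e15).
#' @param k_folds Number of contiguous cross-validation folds (default 3).
#' @param standardize Standardize columns before penalizing (default TRUE).
#' @param seed Retained for provenance; fold assignment is deterministic.
#' @return A `trf_model`: `weights`, `intercept`, `lambda`, `cv_curve`
#'   (tibble: lambda, mean validation MSE, per-fold MSE), `n_lags` (if the
#'   design carries it), `degenerate` flag.
#' @export
fit_trf <- function(design, counts, lambda_grid = default_lambda_grid(),
                    k_folds = 3L, standardize = TRUE, seed = 1L) {
  design <- as.matrix(design)
  counts <- as.numeric(counts)
  stopifnot(nrow(design) == length(counts), k_folds >= 2)
  if (nrow(design) < 2 * k_folds) {
    abort("need at least 2 * k_folds samples to cross-validate")
  }
  lambda_grid <- sort(lambda_grid)
  fit <- fit_trf_multi(design, matrix(counts, ncol = 1), lambda_grid,
                       k_folds, standardize)
  new_trf_model(weights = fit$weights[, 1], intercept = fit$intercept[1],
                lambda = fit$lambda[1], cv_curve = fit$cv_curves[[1]],
                lambda_grid = lambda_grid, k_folds = k_folds,
                degenerate = fit$degenerate, seed = seed)
}

new_trf_model <- function(weights, intercept, lambda, cv_curve,
                          lambda_grid, k_folds, degenerate, seed) {
  structure(list(weights = weights, intercept = intercept, lambda = lambda,
                 cv_curve = cv_curve, lambda_grid = lambda_grid,
                 k_folds = k_folds, degenerate = degenerate, seed = seed),
            class = "trf_model")
}

# shared fitting core: Y may hold many units (columns) over one design.
# Returns original-scale weights (p x u), intercepts, chosen lambda and cv
# curve per unit. SVD is computed once per fold and shared across the
# whole lambda grid and all units.
fit_trf_multi <- function(design, Y, lambda_grid = default_lambda_grid(),
                          k_folds = 3L, standardize = TRUE) {
  n <- nrow(design); p <- ncol(design); u <- ncol(Y)
  col_sd <- apply(design, 2, sd)
  degenerate <- all(col_sd == 0)
  if (degenerate) {
    return(list(weights = matrix(0, p, u), intercept = colMeans(Y),
                lambda = rep(lambda_grid[1], u),
                cv_curves = rep(list(tibble::tibble(
                  lambda = lambda_grid, mean_mse = NA_real_)), u),
                degenerate = TRUE))
  }
  folds <- contiguous_folds(n, k_folds)
  n_lam <- length(lambda_grid)
  val_mse <- array(NA_real_, dim = c(n_lam, k_folds, u))
  for (k in seq_len(k_folds)) {
    tr <- which(folds != k); va <- which(folds == k)
    sol <- ridge_path(design[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                      lambda_grid, standardize)
    for (li in seq_len(n_lam)) {
      pred <- design[va, , drop = FALSE] %*% sol$W[, , li] +
        rep(sol$b[li, ], each = length(va))
      val_mse[li, k, ] <- colMeans((Y[va, , drop = FALSE] - pred)^2)
    }
  }
  mean_mse <- apply(val_mse, c(1, 3), mean)      # n_lam x u
  best <- apply(mean_mse, 2, which.min)
  full <- ridge_path(design, Y, lambda_grid, standardize)
  W <- matrix(0, p, u); b <- numeric(u)
  for (j in seq_len(u)) {
    W[, j] <- full$W[, j, best[j]]
    b[j] <- full$b[best[j], j]
  }
  cv_curves <- lapply(seq_len(u), function(j) {
    tibble::tibble(lambda = lambda_grid, mean_mse = mean_mse[, j],
                   fold_mse = lapply(seq_len(n_lam),
                                     function(li) val_mse[li, , j]))
  })
  list(weights = W, intercept = b, lambda = lambda_grid[best],
       cv_curves = cv_curves, degenerate = FALSE)
}

contiguous_folds <- function(n, k) {
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  rep(seq_len(k), sizes)
}

# ridge solutions for every lambda at once via one SVD.
# Returns W: p x u x n_lam (original scale), b: n_lam x u intercepts.
ridge_path <- function(X, Y, lambdas, standardize = TRUE) {
  n <- nrow(X); p <- ncol(X); u <- ncol(Y)
  mu_x <- colMeans(X)
  sd_x <- if (standardize) apply(X, 2, sd) else rep(1, p)
  sd_x[sd_x == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, `/`)
  mu_y <- colMeans(Y)
  Yc <- sweep(Y, 2, mu_y)
  sv <- svd(Xs, nu = min(n, p), nv = min(n, p))
  keep <- sv$d > max(sv$d[1], 0) * 1e-12
  d <- sv$d[keep]
  Uty <- crossprod(sv$u[, keep, drop = FALSE], Yc)   # r x u
  W <- array(0, dim = c(p, u, length(lambdas)))
  b <- matrix(0, length(lambdas), u)
  V <- sv$v[, keep, drop = FALSE]
  for (li in seq_along(lambdas)) {
    shrink <- d / (d^2 + lambdas[li])
    Ws <- V %*% (shrink * Uty)        # standardized-scale weights
    Wo <- Ws / sd_x                   # back to original scale
    W[, , li] <- Wo
    b[li, ] <- mu_y - as.numeric(crossprod(Wo, mu_x))
  }
  list(W = W, b = b)
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %d weights, lambda = %g%s\n",
              length(x$weights), x$lambda,
              if (isTRUE(x$degenerate)) " (degenerate design)" else ""))
  invisible(x)
}

#' Predict binned responses from a fitted TRF
#'
#' @param object A `trf_model`.
#' @param newdata A design matrix with the model's number of columns, or a
#'   `feature_matrix` / list of them plus `spec` to build the lagged design
#'   here.
#' @param spec A [lag_spec()] when `newdata` is a feature matrix.
#' @param ... Unused.
#' @return Numeric vector of real-valued predicted counts (not clipped or
#'   rounded), one per time bin.
#' @export
predict.trf_model <- function(object, newdata, spec = NULL, ...) {
  if (inherits(newdata, "feature_matrix") ||
      (is.list(newdata) && !is.data.frame(newdata) && !is.matrix(newdata))) {
    if (is.null(spec)) abort("supply a lag_spec to predict from features")
    newdata <- build_lagged_design(newdata, spec)
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights)) {
    abort(sprintf("design has %d columns but the model has %d weights",
                  ncol(newdata), length(object$weights)))
  }
  as.numeric(newdata %*% object$weights + object$intercept)
}

#' @rdname fit_trf
#' @param x A `trf_model`.
#' @param ... Unused.
#' @export
tidy.trf_model <- function(x, ...) {
  tibble::tibble(term = seq_along(x$weights), weight = x$weights)
}

#' @rdname fit_trf
#' @export
glance.trf_model <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    cv_mse = if (all(is.na(x$cv_curve$mean_mse))) NA_real_ else
      min(x$cv_curve$mean_mse, na.rm = TRUE),
    n_weights = length(x$weights),
    degenerate = isTRUE(x$degenerate)
  )
}
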