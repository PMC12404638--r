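# shared small fixtures, built once per test run

fm_values_test <- function(x) {
  y <- unclass(x)
  attr(y, "sampling_rate") <- NULL
  y
}
unclass_fm <- fm_values_test

# memoise expensive fixtures within one session
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_session <- function() {
  fixture("tiny_session", simulate_session(
    n_single = 16, n_repeat_stimuli = 5, n_repeats = 6,
    duration_mean = 1.2, n_units = 6, n_layers = 3,
    strides = c(1, 1, 2), layer_dims = 5, seed = 11))
}

tiny_reliability <- function() {
  fixture("tiny_reliability",
          session_reliability(tiny_session()$responses, R = 1500, seed = 12))
}

tiny_scores <- function() {
  fixture("tiny_scores",
          session_scores(tiny_session(), tiny_reliability(),
                         variants = c("trained", "untrained"),
                         units = tiny_session()$units$unit_id, seed = 13))
}

# Poisson repeat responses with a shared per-bin rate (stimulus-locked
# signal) for direct reliability checks
poisson_repeats <- function(n_stim, n_trials, n_bins, rate_mean,
                            rate_sd = 0, seed = 1) {
  set.seed(seed)
  out <- lapply(seq_len(n_stim), function(s) {
    rate <- pmax(rate_mean + rate_sd * rnorm(n_bins), 0)
    t(vapply(seq_len(n_trials), function(i) rpois(n_bins, rate),
             integer(n_bins)))
  })
  names(out) <- sprintf("stim%02d", seq_len(n_stim))
  out
}

# Gaussian surrogate repeats: shared signal + iid noise per trial
gaussian_repeats <- function(n_stim, n_trials, n_bins, sd_signal, sd_noise,
                             seed = 1) {
  set.seed(seed)
  out <- lapply(seq_len(n_stim), function(s) {
    sig <- rnorm(n_bins, sd = sd_signal)
    t(vapply(seq_len(n_trials),
             function(i) sig + rnorm(n_bins, sd = sd_noise),
             numeric(n_bins)))
  })
  names(out) <- sprintf("stim%02d", seq_len(n_stim))
  out
}

# closed-form ridge with unpenalized intercept (the independent oracle,
# deliberately a different route than the package SVD path)
ridge_oracle <- function(X, y, lambda) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  w <- solve(crossprod(Xc) + diag(lambda, ncol(X)), crossprod(Xc, yc))
  list(weights = as.numeric(w), intercept = ym - sum(xm * w))
}

# textbook BH step-up: reject the m ordered hypotheses with
# p_(i) <= i/m * alpha up to the largest such i
bh_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) / m * alpha)
  out <- rep(FALSE, m)
  if (length(k)) out[ord[seq_len(max(k))]] <- TRUE
  out
}
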