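test_that("waveform synthesis honors length, determinism and spectra", {
  w <- synth_waveform(1.0, 16000, seed = 5)
  expect_length(w, 16000)
  expect_true(all(is.finite(w)) && max(abs(w)) < 1)
  expect_identical(w, synth_waveform(1.0, 16000, seed = 5))

  # pure tone at 1 kHz: spectral peak in the right DFT bin
  tone <- synth_waveform(1.0, 16000, seed = 5, tone_freqs = 1000,
                         noise_level = 0)
  spec <- Mod(fft(tone))[1:8000]
  peak_hz <- which.max(spec) - 1
  expect_lt(abs(peak_hz - 1000), 3)
})

test_that("hierarchy strides set layer rates", {
  base <- feature_matrix(matrix(rnorm(400), 100, 4), 100)
  st1 <- synth_feature_hierarchy(base, 3, c(1, 1, 1), seed = 1)
  expect_equal(vapply(st1$layers, sampling_rate, numeric(1)), rep(100, 3))
  st2 <- synth_feature_hierarchy(base, 3, c(1, 2, 2), seed = 1)
  expect_equal(vapply(st2$layers, sampling_rate, numeric(1)), c(100, 50, 25))
  expect_identical(fm_values_test(st2$layers[[1]]), unclass_fm(base))
  expect_error(synth_feature_hierarchy(base, 2, c(1, 200), seed = 1),
               "stride")
})

test_that("small-weight layers are nearly linear maps of their input", {
  base <- feature_matrix(matrix(rnorm(3000), 500, 6), 100)
  st <- synth_feature_hierarchy(base, 2, c(1, 1), seed = 3,
                                mode = "untrained")
  l1 <- st$layers[[1]]
  l2 <- fm_values_test(st$layers[[2]])
  # least-squares fit of layer 2 dim 1 from the lagged layer 1 (the
  # convolution window) captures most variance when weights are in the
  # linear regime of tanh
  lagged <- build_lagged_design(l1, lag_spec(0.05, 100))  # 5 lags @ 100 Hz
  fit <- lm.fit(cbind(1, lagged), l2[, 1])
  r2 <- 1 - sum(fit$residuals^2) / sum((l2[, 1] - mean(l2[, 1]))^2)
  expect_gt(r2, 0.8)
})

test_that("perturbation modes behave as specified", {
  base <- feature_matrix(matrix(rnorm(2400), 400, 6), 100)
  st <- synth_feature_hierarchy(base, 3, c(1, 1, 1), seed = 2)

  # permuting all-equal weights is a no-op on the features
  st_eq <- st
  st_eq$weights <- lapply(st$weights, function(w) {
    if (is.null(w)) NULL else array(0.05, dim = dim(w))
  })
  st_eq$layers <- encodetrf:::apply_hierarchy(st_eq$base, st_eq$weights,
                                              st_eq$strides)
  perm <- perturb_hierarchy(st_eq, "permute", seed = 9)
  expect_equal(fm_values_test(perm$layers[[3]]),
               fm_values_test(st_eq$layers[[3]]))

  # reinitialization is deterministic in the seed
  r1 <- perturb_hierarchy(st, "reinitialize", seed = 4)
  r2 <- perturb_hierarchy(st, "reinitialize", seed = 4)
  expect_identical(r1$weights, r2$weights)
  expect_error(perturb_hierarchy(st, "rot13"), "arg")
})

test_that("permuting trained weights degrades deep-layer linearity more than reinitializing", {
  base <- feature_matrix(matrix(rnorm(6000), 1000, 6), 100)
  st <- synth_feature_hierarchy(base, 3, c(1, 1, 1), seed = 8,
                                mode = "trained")
  r2_of <- function(stack) {
    X <- build_lagged_design(stack$layers[[3]], lag_spec(0.09, 100))
    b <- fm_values_test(stack$base)
    mean(vapply(seq_len(ncol(b)), function(j) {
      fit <- lm.fit(cbind(1, X), b[, j])
      1 - sum(fit$residuals^2) / sum((b[, j] - mean(b[, j]))^2)
    }, numeric(1)))
  }
  reinit <- perturb_hierarchy(st, "reinitialize", seed = 30)
  permut <- perturb_hierarchy(st, "permute", seed = 30)
  expect_gt(r2_of(reinit), r2_of(permut))
})

test_that("gain-0 units emit unlocked Poisson counts at the baseline rate", {
  sch <- make_schedule(0, 2, 40, duration_mean = 1.0, seed = 1)
  base <- feature_matrix(matrix(rnorm(200), 100, 2), 100)
  stacks <- lapply(seq_len(2), function(i)
    synth_feature_hierarchy(base, 2, c(1, 1), seed = i))
  names(stacks) <- sch$stimuli$stimulus_id
  unit <- list(unit_id = "u1", target_layer = 2L,
               true_trf = matrix(rnorm(10), 2, 5), gain = 0,
               baseline_rate = 10)
  resp <- simulate_unit_responses(unit, stacks, sch, bin_width = 0.05,
                                  seed = 2)
  counts <- unlist(lapply(resp$counts, as.vector))
  # expected count per 50-ms bin at 10 spikes/s is 0.5
  expect_lt(abs(mean(counts) - 0.5), 0.05)
  # Poisson marginal: variance/mean ratio near 1
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.1)
  # no stimulus locking: trials are uncorrelated
  rr <- repeat_responses(resp, "u1")
  r <- cor(rr[[1]][1, ], rr[[1]][2, ])
  expect_lt(abs(r), 0.5)
})

test_that("trial-to-trial correlation matches the Poisson law-of-total-variance prediction", {
  # per-bin rate with variance sigma_s^2 about mean m (in counts):
  # expected trial-to-trial correlation sigma_s^2 / (sigma_s^2 + m)
  set.seed(41)
  n_bins <- 100000
  lam <- pmax(1.0 + 0.8 * rnorm(n_bins), 0)
  y1 <- rpois(n_bins, lam)
  y2 <- rpois(n_bins, lam)
  expected <- var(lam) / (var(lam) + mean(lam))
  expect_lt(abs(cor(y1, y2) - expected), 0.02)

  # the generator realizes the same law: repeats share the rate
  s <- tiny_session()
  u <- s$units[1, ]
  rr <- repeat_responses(s$responses, u$unit_id)
  pred <- true_rate_predictions(s, u$unit_id)
  lam_all <- unlist(pred)
  y_a <- unlist(lapply(rr, function(m) m[1, ]))
  y_b <- unlist(lapply(rr, function(m) m[2, ]))
  expected <- var(lam_all) / (var(lam_all) + mean(lam_all))
  expect_lt(abs(cor(y_a, y_b) - expected), 0.25)
})

test_that("session simulation is deterministic and well-formed", {
  a <- simulate_session(n_single = 6, n_repeat_stimuli = 3, n_repeats = 4,
                        n_units = 3, seed = 5)
  b <- simulate_session(n_single = 6, n_repeat_stimuli = 3, n_repeats = 4,
                        n_units = 3, seed = 5)
  expect_identical(a$responses$counts, b$responses$counts)
  expect_identical(a$units, b$units)
  bins <- schedule_bins(a$schedule, a$bin_width)
  for (p in seq_along(a$responses$counts)) {
    sid <- a$schedule$order$stimulus_id[p]
    expect_equal(ncol(a$responses$counts[[p]]), unname(bins[[sid]]))
    expect_true(all(a$responses$counts[[p]] >= 0))
  }
})
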