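test_that("pair sequences concatenate to the design lengths", {
  rr <- poisson_repeats(10, 3, 32, rate_mean = 1)
  p <- sample_pair_sequences(rr, seed = 1)
  expect_length(p$U, 320)
  expect_length(p$V, 320)

  rr2 <- poisson_repeats(11, 4, 20, rate_mean = 1)
  p2 <- sample_pair_sequences(rr2, seed = 1)
  expect_length(p2$U, 220)

  # single stimulus with exactly two trials: the unique unordered pair
  rr3 <- list(s1 = rbind(1:6, 7:12))
  p3 <- sample_pair_sequences(rr3, seed = 2)
  expect_setequal(c(p3$U[1], p3$V[1]), c(1, 7))
  expect_error(sample_pair_sequences(list(s1 = rbind(1:4)), seed = 1),
               ">= 2 trials")
})

test_that("the circular-shift null transform matches its definition", {
  expect_equal(null_transform(c(1, 2, 3, 4)), c(3, 4, 1, 2))
  v <- rnorm(100)
  expect_equal(null_transform(null_transform(v)), v)   # involution, even n
  expect_equal(sort(null_transform(v)), sort(v))       # marginals preserved
  v5 <- c(10, 20, 30, 40, 50)
  expect_equal(null_transform(v5), c(30, 40, 50, 10, 20))
})

test_that("reliability distributions recover limiting cases", {
  # identical nonconstant trials: true distribution at exactly 1
  rr <- lapply(1:3, function(s) {
    row <- rpois(30, 2) + rep(c(0, 5), 15)
    rbind(row, row, row)
  })
  names(rr) <- paste0("s", 1:3)
  d <- reliability_distributions(rr, R = 200, seed = 1)
  expect_true(all(abs(d$true$values - 1) < 1e-12))

  # unlocked Poisson unit: both means near 0 (the tolerance covers the
  # data-conditional component: a finite trial set correlates by chance)
  rr0 <- poisson_repeats(10, 8, 64, rate_mean = 1, seed = 3)
  d0 <- reliability_distributions(rr0, R = 3000, seed = 4)
  expect_lt(abs(mean(d0$true$values)), 0.03)
  expect_lt(abs(mean(d0$null$values)), 0.03)
})

test_that("vectorized resampling matches a literal per-resample reference", {
  rr <- gaussian_repeats(4, 5, 25, sd_signal = 1, sd_noise = 1, seed = 6)
  d <- reliability_distributions(rr, R = 4000, seed = 7)

  # independent naive reference: loop the published procedure directly
  set.seed(99)
  naive <- replicate(4000, {
    ord <- sample(seq_along(rr))
    pair <- lapply(rr[ord], function(y) {
      ij <- sample(nrow(y), 2)
      list(u = y[ij[1], ], v = y[ij[2], ])
    })
    u <- unlist(lapply(pair, `[[`, "u"))
    v <- unlist(lapply(pair, `[[`, "v"))
    c(cor(u, v), cor(u, null_transform(v)))
  })
  expect_lt(abs(mean(d$true$values) - mean(naive[1, ])), 0.02)
  expect_lt(abs(sd(d$true$values) - sd(naive[1, ])), 0.02)
  expect_lt(abs(mean(d$null$values) - mean(naive[2, ])), 0.02)
})

test_that("ceiling estimates match the Gaussian signal/noise ratio", {
  sd_s <- 1; sd_n <- 1.5
  expected <- sd_s^2 / (sd_s^2 + sd_n^2)
  rr <- gaussian_repeats(5, 4, 800, sd_s, sd_n, seed = 8)
  d <- reliability_distributions(rr, R = 1500, seed = 9)
  expect_lt(abs(mean(d$true$values) - expected), 0.03)
})

test_that("tuned test and well-tuned criterion behave at their boundaries", {
  v <- rnorm(500)
  expect_equal(tuned_test(v, v), 0.5, tolerance = 1e-3)
  expect_lt(tuned_test(v + 10, v), 1e-10)

  # inclusive boundary: gap exactly delta * sd(null) passes
  null <- rep(c(-1, 1) * 0.1, 250)            # mean 0, known sd
  truev <- null + 0.5 * sd(null)
  expect_true(well_tuned(truev, null, delta = 0.5))
  # monotone in delta
  truev2 <- null + 0.7 * sd(null)
  expect_true(well_tuned(truev2, null, delta = 0.5))
  expect_false(well_tuned(truev2, null, delta = 1.0))
  expect_error(well_tuned(truev, rep(0.3, 100)), "zero variance")
})

test_that("accepted-unit count is non-increasing in delta", {
  rel <- tiny_reliability()
  deltas <- c(0, 0.25, 0.5, 1, 2, 4)
  counts <- vapply(deltas, function(d) {
    sum(rel$gap >= d & rel$tuned_p < 0.05)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("noise correction follows the square-root-of-ceiling rule", {
  expect_equal(noise_correct(0.3, 0.36), 0.5)
  expect_equal(noise_correct(0.42, 1.0), 0.42)
  expect_true(is.na(noise_correct(0.3, 1e-4)))       # uncorrectable, flagged
  expect_equal(noise_correct(c(0.2, 0.3), c(0.25, 0.25)), c(0.4, 0.6))
})

test_that("undefined (constant-sequence) resamples are excluded and counted", {
  rr <- list(s1 = rbind(c(1:9, 5), c(9:1, 5), rep(1, 10)))
  d <- reliability_distributions(rr, R = 300, seed = 5)
  expect_gt(d$true$n_excluded, 0)
  expect_true(all(is.finite(d$true$values)))
  rr_const <- list(s1 = rbind(rep(1, 10), rep(1, 10)))
  expect_error(reliability_distributions(rr_const, R = 50, seed = 1),
               "undefined")
})
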