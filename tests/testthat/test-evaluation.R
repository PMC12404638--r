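test_that("long-sequence assembly preserves order and repeat structure", {
  rr <- poisson_repeats(10, 11, 32, rate_mean = 1, seed = 1)
  preds <- lapply(rr, function(y) colMeans(y))
  seqs <- assemble_long_sequences(rr, preds)
  expect_length(seqs$responses, 11)
  expect_length(seqs$model, 320)
  expect_true(all(lengths(seqs$responses) == 320))

  rr15 <- poisson_repeats(11, 15, 20, rate_mean = 1, seed = 2)
  seqs15 <- assemble_long_sequences(rr15, lapply(rr15, colMeans))
  expect_length(seqs15$responses, 15)

  # degenerate: one stimulus, two repeats
  one <- list(s1 = rbind(c(1, 2, 3), c(4, 5, 6)))
  s1 <- assemble_long_sequences(one, list(s1 = c(0.5, 1, 2)))
  expect_equal(s1$responses[[1]], c(1, 2, 3))
  expect_equal(s1$responses[[2]], c(4, 5, 6))

  ragged <- list(a = rbind(1:3, 4:6), b = rbind(1:3, 4:6, 7:9))
  expect_error(assemble_long_sequences(ragged, list(a = 1:3, b = 1:3)),
               "\\bb\\b")
  expect_error(assemble_long_sequences(one, list()), "s1")
})

test_that("unit scoring reports per-repeat, mean, and corrected correlations", {
  y <- rpois(100, 3) + 1
  perfect <- score_unit(y, list(y, y, y), ceiling = 0.64)
  expect_equal(perfect$mean_r, 1)
  expect_equal(perfect$corrected_r, 1.25)   # 1 / sqrt(0.64)
  expect_equal(lengths(perfect$per_repeat_r), 3)

  # independent model: correlation near zero
  set.seed(5)
  r0 <- replicate(300, {
    score_unit(rnorm(50), list(rnorm(50)), ceiling = 1)$mean_r
  })
  expect_lt(abs(mean(r0)), 0.02)

  flagged <- score_unit(rep(1, 10), list(rnorm(10)), ceiling = 0.5)
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$mean_r))
})

test_that("oracle (true-rate) models approach a corrected correlation of 1", {
  s <- tiny_session()
  rel <- tiny_reliability()
  corrected <- vapply(s$units$unit_id, function(uid) {
    pred <- true_rate_predictions(s, uid)
    rr <- repeat_responses(s$responses, uid)
    seqs <- assemble_long_sequences(rr, pred)
    score_unit(seqs$model, seqs$responses,
               rel$ceiling[rel$unit_id == uid])$corrected_r
  }, numeric(1))
  expect_gt(median(corrected), 0.9)
  expect_lt(median(abs(corrected - 1)), 0.15)
})

test_that("paired model comparisons apply signed-rank tests with BH control", {
  set.seed(21)
  n <- 50
  base <- tibble::tibble(unit_id = sprintf("u%02d", 1:n),
                         variant = "strf", layer = NA_integer_,
                         corrected_r = runif(n, 0.2, 0.6))
  mk <- function(variant, layer, shift) {
    tibble::tibble(unit_id = base$unit_id, variant = variant, layer = layer,
                   corrected_r = base$corrected_r + shift)
  }
  scores <- dplyr::bind_rows(
    base,
    mk("trained", 1L, 0.2), mk("untrained", 1L, 0),
    mk("trained", 2L, 0),   mk("untrained", 2L, 0))
  out <- compare_models(scores, alpha = 0.01)
  expect_equal(nrow(out), 4)   # 2 x L with L = 2
  r1 <- out[out$layer == 1 & out$comparison == "trained_vs_untrained", ]
  expect_lt(r1$p_value, 1e-6)
  expect_true(r1$significant)
  expect_equal(r1$direction, 1)
  # identical paired vectors: p = 1, no star
  r2 <- out[out$layer == 2 & out$comparison == "trained_vs_untrained", ]
  expect_equal(r2$p_value, 1)
  expect_false(r2$significant)

  # pairing integrity: permuting unit order changes nothing
  scores_perm <- scores[sample(nrow(scores)), ]
  out_perm <- compare_models(scores_perm, alpha = 0.01)
  expect_equal(out_perm$p_value, out$p_value)

  # unpaired inputs are rejected
  broken <- scores[!(scores$variant == "untrained" &
                       scores$unit_id == "u01"), ]
  expect_error(compare_models(broken), "unpaired")
})

test_that("BH decisions match the textbook step-up rule", {
  set.seed(31)
  for (i in 1:1000) {
    m <- 2 * sample(2:8, 1)             # 2 x L families
    p <- runif(m)^sample(1:3, 1)        # mix of null-ish and skewed draws
    expect_identical(bh_significant(p, 0.05), bh_oracle(p, 0.05))
  }
})

test_that("correlation ratios cancel the common ceiling normalizer", {
  expect_equal(correlation_ratio(0.6, 0.4), 1.5)
  expect_equal(correlation_ratio(0.4, 0.4), 1.0)
  expect_true(is.na(correlation_ratio(0.3, 0)))
  # identical whether computed from corrected or raw correlations
  raw_m <- 0.33; raw_s <- 0.21; ceiling <- 0.49
  expect_equal(
    correlation_ratio(noise_correct(raw_m, ceiling),
                      noise_correct(raw_s, ceiling)),
    correlation_ratio(raw_m, raw_s))
})
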