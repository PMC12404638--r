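test_that("cochleagram frontend localizes tones and respects log scaling", {
  sr <- 16000
  tone <- synth_waveform(0.5, sr, seed = 1, tone_freqs = 1000,
                         noise_level = 0)
  cg <- cochleagram(tone, sr, n_filters = 64)
  cfs <- attr(cg, "center_frequencies")
  expect_equal(ncol(cg), 64)
  expect_true(!is.unsorted(cfs))
  expect_true(min(cfs) >= 50 - 1e-6 && max(cfs) <= 8000 + 1e-6)
  # per-frame argmax channel should sit at the CF nearest 1 kHz
  interior <- 3:(nrow(cg) - 3)
  peak_ch <- apply(unclass_fm(cg)[interior, , drop = FALSE], 1, which.max)
  target <- which.min(abs(cfs - 1000))
  expect_true(all(abs(peak_ch - target) <= 1))

  # doubling amplitude shifts log output by a constant
  cg2 <- cochleagram(2 * tone, sr, n_filters = 64)
  shift <- unclass_fm(cg2) - unclass_fm(cg)
  hot <- unclass_fm(cg) > min(unclass_fm(cg)) + 1e-6  # off-floor cells
  expect_lt(diff(range(shift[hot])), 1e-6)
  expect_equal(mean(shift[hot]), log(2), tolerance = 1e-6)
})

test_that("cochleagram of silence sits at the log floor and errors are raised", {
  cg <- cochleagram(numeric(800), 16000, n_filters = 16)
  expect_equal(diff(range(unclass_fm(cg))), 0)
  expect_error(cochleagram(rnorm(100), 16000, fmin = 9000, fmax = 8000),
               "fmin")
  expect_error(cochleagram(rnorm(100), 8000), "Nyquist")
})

test_that("ERB center-frequency spacing matches the ERB-rate formula", {
  cfs <- erb_space(50, 8000, 211)
  expect_length(cfs, 211)
  erb <- function(f) 21.4 * log10(1 + 0.00437 * f)   # independent rewrite
  steps <- diff(erb(cfs))
  expect_lt(diff(range(steps)), 1e-9)                # uniform on ERB scale
  expect_equal(cfs[1], 50, tolerance = 1e-6)
  expect_equal(cfs[211], 8000, tolerance = 1e-3)
})

test_that("feature resampling preserves band-limited content", {
  # length arithmetic and identity
  fm <- feature_matrix(matrix(rnorm(300), 100, 3), 100)
  out <- resample_features(fm, 20)
  expect_equal(nrow(out), 20)
  expect_equal(sampling_rate(out), 20)
  expect_equal(unclass_fm(resample_features(fm, 100)), unclass_fm(fm))

  # 2-Hz sinusoid resampled 100 -> 20 Hz against the closed form
  t_src <- (0:499) / 100
  x <- feature_matrix(sin(2 * pi * 2 * t_src), 100)
  y <- resample_features(x, 20)
  t_tgt <- (0:(nrow(y) - 1)) / 20
  interior <- 8:(nrow(y) - 8)
  expect_lt(max(abs(unclass_fm(y)[interior, 1] -
                    sin(2 * pi * 2 * t_tgt[interior]))), 0.02)

  # constant input stays constant (within edge tolerance)
  cf <- resample_features(feature_matrix(rep(3, 100), 100), 20)
  expect_lt(max(abs(unclass_fm(cf) - 3)), 1e-6)

  # down-then-up round trip on a band-limited signal
  z <- feature_matrix(sin(2 * pi * 3 * t_src), 100)
  back <- resample_features(resample_features(z, 50), 100)
  mid <- 30:470
  expect_lt(max(abs(unclass_fm(back)[mid, 1] - unclass_fm(z)[mid, 1])), 0.02)
})

test_that("zero-phase low-pass attenuates the stopband and passes DC", {
  rate <- 50
  t <- (0:999) / rate
  mix <- feature_matrix(sin(2 * pi * 1 * t) + sin(2 * pi * 12 * t), rate)
  filt <- lowpass(mix, 5)
  spec <- Mod(fft(unclass_fm(filt)[, 1]))
  f_axis <- (seq_along(t) - 1) * rate / length(t)
  amp_at <- function(f) max(spec[abs(f_axis - f) < 0.05])
  expect_gt(amp_at(1) / amp_at(12), 100)   # 12 Hz crushed, 1 Hz kept

  # DC preservation and Nyquist pass-through
  const <- feature_matrix(rep(2.5, 200), rate)
  expect_lt(max(abs(unclass_fm(lowpass(const, 10)) - 2.5)), 1e-4)
  expect_equal(unclass_fm(lowpass(mix, 25)), unclass_fm(mix))
  expect_error(lowpass(mix, 26), "Nyquist")
  expect_error(lowpass(mix, 0), "positive")

  # filtering at c then at c' >= c equals filtering at c (idempotence)
  once <- lowpass(mix, 5)
  twice <- lowpass(once, 15)
  expect_equal(unclass_fm(twice), unclass_fm(once), tolerance = 0.02)
})
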