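#' ERB-spaced cochleagram
#'
#' Time-frequency analysis with a bank of gammatone-magnitude filters whose
#' center frequencies are spaced uniformly on the ERB-rate scale, the
#' default frontend for STRF baselines. Frames are Hann-windowed with
#' `1 - overlap` hop (87.5% overlap and a 20-Hz frame rate give a 400-ms
#' window and 50-ms hop); per frame, the power spectrum is weighted by each
#' filter's squared magnitude response and the resulting channel amplitudes
#' are log-compressed after clipping at a small fraction of the global
#' maximum (log scaling of the spectrum matters a great deal for predictive
#' power downstream).
#'
#' @param waveform Numeric vector of audio samples.
#' @param sample_rate Audio sampling rate, Hz; must be >= `2 * fmax`.
#' @param n_filters Number of filters (default 211).
#' @param fmin,fmax Frequency range of the filterbank, Hz (defaults 50-8000).
#' @param overlap Fractional frame overlap in (0, 1), default 0.875.
#' @param frame_rate Output frame rate, Hz; the window length is
#'   `1 / (frame_rate * (1 - overlap))`.
#' @param log_floor_frac Clipping floor before the log, as a fraction of the
#'   maximum channel amplitude.
#' @return A `cochleagram`: a `feature_matrix` (frames x filters) with
#'   attributes `center_frequencies` (Hz) and `frame_times` (s).
#' @export
cochleagram <- function(waveform, sample_rate, n_filters = 211L,
                        fmin = 50, fmax = 8000, overlap = 0.875,
                        frame_rate = 20,
                        log_floor_frac = .encodetrf_defaults$log_floor_frac) {
  stopifnot(is.numeric(waveform), length(waveform) > 0,
            overlap > 0, overlap < 1, frame_rate > 0, n_filters >= 1)
  if (fmin >= fmax) abort("fmin must be below fmax")
  if (sample_rate < 2 * fmax) {
    abort("sample_rate must be at least 2 * fmax (Nyquist)")
  }
  hop <- as.integer(round(sample_rate / frame_rate))
  win_len <- as.integer(round(hop / (1 - overlap)))
  cfs <- erb_space(fmin, fmax, n_filters)

  n <- length(waveform)
  n_frames <- max(1L, as.integer(ceiling(n / hop)))
  # center-padded framing: frame t covers samples around (t - 1) * hop
  pad <- win_len %/% 2L
  x <- c(numeric(pad), waveform, numeric(win_len + pad))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(win_len) / (win_len + 1))
  frames <- vapply(seq_len(n_frames), function(t) {
    i0 <- (t - 1L) * hop + 1L
    x[i0:(i0 + win_len - 1L)] * win
  }, numeric(win_len))
  spec <- stats::mvfft(frames)
  n_half <- win_len %/% 2L + 1L
  power <- Mod(spec[seq_len(n_half), , drop = FALSE])^2
  freqs <- (seq_len(n_half) - 1) * sample_rate / win_len
  gains2 <- vapply(cfs, function(cf) gammatone_gain(freqs, cf)^2,
                   numeric(n_half))
  amp <- sqrt(t(power) %*% gains2)      # frames x filters
  floor_val <- max(amp) * log_floor_frac
  if (floor_val <= 0) floor_val <- .Machine$double.xmin
  logamp <- log(pmax(amp, floor_val))
  out <- feature_matrix(logamp, frame_rate)
  attr(out, "center_frequencies") <- cfs
  attr(out, "frame_times") <- (seq_len(n_frames) - 1) / frame_rate
  class(out) <- c("cochleagram", class(out))
  out
}

#' @export
print.cochleagram <- function(x, ...) {
  cfs <- attr(x, "center_frequencies")
  cat(sprintf("<cochleagram> %d frames x %d filters (%.0f-%.0f Hz) @ %g Hz\n",
              nrow(x), ncol(x), min(cfs), max(cfs), sampling_rate(x)))
  invisible(x)
}

# ERB-rate scale (Glasberg & Moore): erb(f) = 21.4 log10(1 + 0.00437 f)
erb_rate <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' ERB-spaced center frequencies
#' @param fmin,fmax Range in Hz.
#' @param n Number of frequencies.
#' @return Ascending numeric vector of length `n`.
#' @export
erb_space <- function(fmin, fmax, n) {
  erb_rate_inv(seq(erb_rate(fmin), erb_rate(fmax), length.out = n))
}

# 4th-order gammatone magnitude response around center frequency cf
gammatone_gain <- function(f, cf, order = 4) {
  erb_bw <- 24.7 * (4.37 * cf / 1000 + 1)
  b <- 1.019 * erb_bw
  (1 + ((f - cf) / b)^2)^(-order / 2)
}

#' Resample a feature matrix to a new rate
#'
#' Band-limited resampling by windowed-sinc interpolation, applied per
#' dimension: each output frame is a Hann-windowed sinc average of input
#' frames, with the sinc cutoff at the lower of the two Nyquist rates and
#' the kernel renormalized to unit sum (so constant inputs are reproduced
#' exactly, including at the edges). The output has
#' `round(n * target_rate / source_rate)` frames.
#'
#' @param fm A `feature_matrix`.
#' @param target_rate Target rate in Hz, > 0.
#' @param taps Half-width of the interpolation kernel, in output-Nyquist
#'   periods (default 8; larger is more accurate and slower).
#' @return A `feature_matrix` at `target_rate`.
#' @export
resample_features <- function(fm, target_rate, taps = 8L) {
  stopifnot(inherits(fm, "feature_matrix"), target_rate > 0)
  src <- sampling_rate(fm)
  x <- fm_values(fm)
  if (isTRUE(all.equal(target_rate, src))) {
    return(feature_matrix(x, target_rate))
  }
  W <- sinc_weights(nrow(x), src, target_rate, taps)
  feature_matrix(W %*% x, target_rate)
}

# n_out x n_in interpolation matrix; rows sum to 1
sinc_weights <- function(n_in, src, target, taps) {
  n_out <- max(1L, as.integer(round(n_in * target / src)))
  ratio <- target / src
  cutoff <- min(1, ratio)                 # in units of source Nyquist pairs
  half <- max(4, ceiling(taps / cutoff))  # input samples per side
  centers <- (seq_len(n_out) - 1) / ratio # 0-based input positions
  W <- matrix(0, n_out, n_in)
  for (m in seq_len(n_out)) {
    lo <- max(1L, floor(centers[m]) - half + 1L)
    hi <- min(n_in, ceiling(centers[m]) + half + 1L)
    d <- (lo:hi) - 1 - centers[m]
    h <- cutoff * sinc(cutoff * d) * (0.5 + 0.5 * cos(pi * d / (half + 1)))
    W[m, lo:hi] <- h / sum(h)
  }
  W
}

sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))

#' Zero-phase low-pass filtering of features
#'
#' Forward-backward Butterworth filtering per dimension (zero phase lag, so
#' temporal alignment with the response is preserved). Used by the
#' time-scale analysis to remove feature structure above a cutoff before
#' refitting the readout. A cutoff at the Nyquist rate returns the input
#' unchanged.
#'
#' @param fm A `feature_matrix`.
#' @param cutoff Cutoff frequency in Hz, in (0, Nyquist].
#' @param order Butterworth order (default 4).
#' @return A `feature_matrix` at the same rate.
#' @export
lowpass <- function(fm, cutoff, order = .encodetrf_defaults$lowpass_order) {
  stopifnot(inherits(fm, "feature_matrix"))
  nyq <- sampling_rate(fm) / 2
  if (cutoff <= 0) abort("cutoff must be positive")
  if (cutoff > nyq + 1e-9) abort("cutoff exceeds the Nyquist frequency")
  x <- fm_values(fm)
  if (isTRUE(all.equal(cutoff, nyq))) {
    return(feature_matrix(x, sampling_rate(fm)))
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  # edge-replicate padding tames filtfilt boundary transients (and keeps
  # constant signals exactly constant)
  pad <- min(nrow(x) - 1L,
             as.integer(ceiling(10 * sampling_rate(fm) / cutoff)))
  y <- apply(x, 2, function(col) {
    padded <- c(rep(col[1], pad), col, rep(col[length(col)], pad))
    signal::filtfilt(bf, padded)[(pad + 1):(pad + length(col))]
  })
  feature_matrix(matrix(y, ncol = ncol(x), dimnames = dimnames(x)),
                 sampling_rate(fm))
}
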