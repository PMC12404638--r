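#' Synthesize a test waveform
#'
#' Mixes a small tone complex with amplitude-modulated noise so that the
#' cochleagram of the result has nontrivial spectrotemporal structure. Used
#' to exercise the STRF frontend without real recordings.
#'
#' @param duration Seconds, > 0.
#' @param sample_rate Hz, >= 16000.
#' @param seed Integer seed; the waveform is bit-identical across calls.
#' @param tone_freqs Tone frequencies in Hz, or `NULL` to draw 3 random
#'   tones log-uniform in 150-6000 Hz.
#' @param noise_level Amplitude of the modulated-noise component relative to
#'   the tones (0 gives a pure tone complex).
#' @return Numeric vector of `round(duration * sample_rate)` samples in
#'   (-1, 1).
#' @export
synth_waveform <- function(duration, sample_rate = 16000, seed = 1L,
                           tone_freqs = NULL, noise_level = 0.5) {
  stopifnot(duration > 0, sample_rate >= 16000, noise_level >= 0)
  withr_seed(seed)
  n <- as.integer(round(duration * sample_rate))
  t <- seq_len(n) / sample_rate
  if (is.null(tone_freqs)) {
    tone_freqs <- exp(runif(3, log(150), log(6000)))
  }
  wave <- numeric(n)
  for (f in tone_freqs) {
    # slow random AM envelope per tone
    env <- 1 + 0.6 * sin(2 * pi * runif(1, 0.5, 3) * t + runif(1, 0, 2 * pi))
    wave <- wave + env * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  }
  wave <- wave / max(length(tone_freqs), 1)
  if (noise_level > 0) {
    noise <- rnorm(n)
    env <- abs(smooth_ma(rnorm(n), max(3L, as.integer(sample_rate / 20))))
    env <- env / max(env)
    wave <- wave + noise_level * env * noise / 3
  }
  wave / max(1, max(abs(wave)) + 1e-12) * 0.9
}

smooth_ma <- function(x, k) {
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2, circular = TRUE))
}

#' Build a synthetic feature hierarchy from base features
#'
#' Emulates the layer structure of a speech network: layer 1 is the base
#' feature matrix (optionally decimated by its stride) and each deeper layer
#' is a saturating nonlinearity (`tanh`) of a random temporal convolution of
#' the previous layer, downsampled by that layer's stride. Sampling rates
#' therefore decline (weakly) with depth, as convolutional strides impose in
#' real networks. The convolution weights are stored on the stack so they
#' can later be re-initialized or permuted.
#'
#' Two weight regimes are available. `"trained"` draws structured kernels —
#' random mixtures of temporal smoothing and differencing filters at
#' saturating scale — standing in for the organized filters of a trained
#' network. `"untrained"` draws small random weights, the usual
#' initialization regime, under which each layer is a nearly linear map of
#' the previous one.
#'
#' @param base A `feature_matrix` (or plain matrix plus `base_rate`).
#' @param n_layers Number of layers, >= 1 (layer 1 is the base).
#' @param strides Positive integer downsampling factor per layer, length
#'   `n_layers`; `strides[1]` decimates the base itself (usually 1).
#' @param seed Integer seed for the weight draw.
#' @param mode `"trained"` or `"untrained"` weight regime.
#' @param dims Output dimensions per layer (recycled); defaults to the base
#'   dimensionality.
#' @param kernel_width Temporal kernel length in frames of the layer below.
#' @param base_rate Sampling rate of `base` if it is a plain matrix.
#' @param weights Optional precomputed weights (as stored on another stack)
#'   to reuse, e.g. to push several stimuli through one hierarchy.
#' @return A `feature_stack`: list with `layers` (list of `feature_matrix`),
#'   `weights`, `strides`, `L`, `base`, `mode`.
#' @export
synth_feature_hierarchy <- function(base, n_layers, strides, seed = 1L,
                                    mode = c("trained", "untrained"),
                                    dims = NULL, kernel_width = 5L,
                                    base_rate = NULL, weights = NULL) {
  mode <- match.arg(mode)
  if (!inherits(base, "feature_matrix")) {
    if (is.null(base_rate)) abort("base_rate required for a plain matrix")
    base <- feature_matrix(base, base_rate)
  }
  stopifnot(n_layers >= 1, length(strides) == n_layers,
            all(strides >= 1), all(strides == as.integer(strides)))
  strides <- as.integer(strides)
  if (is.null(dims)) dims <- ncol(base)
  dims <- rep_len(as.integer(dims), n_layers)
  dims[1] <- ncol(base)
  if (is.null(weights)) {
    weights <- make_hierarchy_weights(dims, n_layers, kernel_width, mode, seed)
  }
  layers <- apply_hierarchy(base, weights, strides)
  structure(list(layers = layers, weights = weights, strides = strides,
                 L = n_layers, base = base, mode = mode,
                 kernel_width = as.integer(kernel_width)),
            class = "feature_stack")
}

# weights[[1]] is NULL (layer 1 is the base); weights[[l]] is an
# dims[l] x dims[l-1] x kernel_width array
make_hierarchy_weights <- function(dims, n_layers, kernel_width, mode, seed) {
  withr_seed(seed)
  k <- as.integer(kernel_width)
  weights <- vector("list", n_layers)
  for (l in seq_len(n_layers)[-1]) {
    d_out <- dims[l]; d_in <- dims[l - 1]
    if (mode == "untrained") {
      w <- array(rnorm(d_out * d_in * k, sd = 0.5 / sqrt(d_in * k)),
                 dim = c(d_out, d_in, k))
    } else {
      # structured kernels: smoothing (hann) and first-difference temporal
      # profiles, sparse input mixing, at a scale that engages the
      # saturating nonlinearity
      hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(k) / (k + 1))
      hann <- hann / sum(hann)
      diffk <- c(diff(hann), 0); diffk <- diffk / max(sum(abs(diffk)), 1e-9)
      w <- array(0, dim = c(d_out, d_in, k))
      for (i in seq_len(d_out)) {
        picks <- sample.int(d_in, min(2L, d_in))
        for (j in picks) {
          prof <- if (runif(1) < 0.5) hann else diffk
          w[i, j, ] <- w[i, j, ] + runif(1, 1.0, 2.0) * sample(c(-1, 1), 1) * prof
        }
      }
    }
    weights[[l]] <- w
  }
  weights
}

apply_hierarchy <- function(base, weights, strides) {
  n_layers <- length(strides)
  layers <- vector("list", n_layers)
  rate <- sampling_rate(base)
  x <- fm_values(base)
  # layer 1: base, decimated by its stride
  if (strides[1] > 1) {
    if (strides[1] > nrow(x)) abort("stride exceeds the time extent of the base")
    x <- x[seq(1, nrow(x), by = strides[1]), , drop = FALSE]
    rate <- rate / strides[1]
  }
  layers[[1]] <- feature_matrix(x, rate)
  for (l in seq_len(n_layers)[-1]) {
    w <- weights[[l]]
    y <- causal_conv(x, w)
    s <- strides[l]
    if (s > nrow(y)) {
      abort(paste0("stride exceeds the remaining time extent at layer ", l))
    }
    if (s > 1) y <- y[seq(1, nrow(y), by = s), , drop = FALSE]
    rate <- rate / s
    x <- tanh(y)
    layers[[l]] <- feature_matrix(x, rate)
  }
  layers
}

# y_t[i] = sum_{j,tau} w[i,j,tau] * x[t - tau + 1, j], zero-padded at onset
causal_conv <- function(x, w) {
  k <- dim(w)[3]
  n <- nrow(x)
  y <- matrix(0, n, dim(w)[1])
  for (tau in seq_len(k)) {
    xs <- shift_down(x, tau - 1L)
    wt <- matrix(w[, , tau], nrow = dim(w)[1], ncol = dim(w)[2])
    y <- y + xs %*% t(wt)
  }
  y
}

# shift rows down by s, zero-filling the top
shift_down <- function(x, s) {
  if (s == 0L) return(x)
  n <- nrow(x)
  rbind(matrix(0, min(s, n), ncol(x)),
        x[seq_len(max(n - s, 0L)), , drop = FALSE])
}

#' Perturb the weights of a feature hierarchy
#'
#' `"reinitialize"` redraws all convolution weights from the small-value
#' initialization scheme; `"permute"` randomly shuffles the existing weight
#' entries within each layer, preserving their marginal distribution while
#' destroying their structure. Features are recomputed from the stored base.
#'
#' @param stack A `feature_stack` with stored weights.
#' @param mode `"reinitialize"` or `"permute"`.
#' @param seed Integer seed.
#' @return A new `feature_stack`.
#' @export
perturb_hierarchy <- function(stack, mode = c("reinitialize", "permute"),
                              seed = 1L) {
  stopifnot(inherits(stack, "feature_stack"))
  mode <- match.arg(mode)
  weights <- perturb_weights(stack$weights, mode, seed,
                             kernel_width = stack$kernel_width)
  layers <- apply_hierarchy(stack$base, weights, stack$strides)
  out <- stack
  out$layers <- layers
  out$weights <- weights
  out$mode <- if (mode == "reinitialize") "untrained" else "permuted"
  out
}

perturb_weights <- function(weights, mode, seed, kernel_width) {
  withr_seed(seed)
  lapply(weights, function(w) {
    if (is.null(w)) return(NULL)
    if (mode == "reinitialize") {
      array(rnorm(length(w), sd = 0.5 / sqrt(dim(w)[2] * dim(w)[3])),
            dim = dim(w))
    } else {
      array(w[sample.int(length(w))], dim = dim(w))
    }
  })
}
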