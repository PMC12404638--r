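#' Draw a ground-truth unit population
#'
#' Each simulated multi-unit is driven by a 250-ms linear readout (its true
#' temporal receptive field) of one hierarchy layer. Primary units draw
#' their target layer from the shallow half of the hierarchy and
#' non-primary units from the deep half, with a 25% cross-over rate — a
#' "soft" hierarchy that the layer-preference analysis should recover
#' without being trivial.
#'
#' The true TRF is smooth across lags; its overall scale is calibrated by
#' [simulate_session()] so the pre-rectification drive has unit variance,
#' making `gain` interpretable in spikes/s.
#'
#' @param n_units Number of units.
#' @param n_layers Hierarchy depth `L`.
#' @param layer_dims Feature dimensions per layer (recycled).
#' @param n_lags Readout window length in bins.
#' @param prop_primary Fraction of units labelled primary.
#' @param crossover Probability a unit draws its target layer from the
#'   other region's half.
#' @param gain_range Uniform range for `gain`, spikes/s per unit drive.
#' @param baseline_range Uniform range for `baseline_rate`, spikes/s.
#' @param target_layer Optional fixed target layer for every unit
#'   (overrides the region-based draw).
#' @param seed Integer seed.
#' @return Tibble with columns `unit_id`, `region` ("primary" /
#'   "non-primary"), `target_layer`, `gain`, `baseline_rate`, and a
#'   list-column `true_trf` (dims x lags matrices).
#' @export
make_units <- function(n_units, n_layers, layer_dims, n_lags = 5L,
                       prop_primary = 0.5, crossover = 0.25,
                       gain_range = c(20, 60), baseline_range = c(2, 10),
                       target_layer = NULL, seed = 1L) {
  stopifnot(n_units >= 1, n_layers >= 1, crossover >= 0, crossover <= 1)
  layer_dims <- rep_len(as.integer(layer_dims), n_layers)
  withr_seed(seed)
  region <- ifelse(seq_len(n_units) <= round(prop_primary * n_units),
                   "primary", "non-primary")
  shallow <- seq_len(max(1L, ceiling(n_layers / 2)))
  deep <- seq.int(min(n_layers, floor(n_layers / 2) + 1L), n_layers)
  tl <- vapply(region, function(r) {
    own <- if (r == "primary") shallow else deep
    other <- if (r == "primary") deep else shallow
    pool <- if (runif(1) < crossover) other else own
    pool[sample.int(length(pool), 1L)]
  }, integer(1))
  if (!is.null(target_layer)) {
    stopifnot(target_layer >= 1, target_layer <= n_layers)
    tl <- rep(as.integer(target_layer), n_units)
  }
  lag_win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_lags) / (n_lags + 1))
  trfs <- lapply(seq_len(n_units), function(i) {
    d <- layer_dims[tl[i]]
    w <- matrix(rnorm(d * n_lags), d, n_lags)
    sweep(w, 2, lag_win, `*`)   # smooth temporal profile
  })
  tibble::tibble(
    unit_id = sprintf("unit%03d", seq_len(n_units)),
    region = unname(region),
    target_layer = unname(tl),
    gain = runif(n_units, gain_range[1], gain_range[2]),
    baseline_rate = runif(n_units, baseline_range[1], baseline_range[2]),
    true_trf = trfs
  )
}

#' Simulate spike-count responses for one ground-truth unit
#'
#' The unit's drive at each bin is its true TRF applied to the lagged
#' target-layer features, resampled to the bin rate. The firing rate is
#' `baseline_rate + gain * max(drive, 0)` (rectification keeps rates
#' non-negative), and counts are drawn independently per presentation from
#' a Poisson law with mean `rate * bin_width` — so repeats share the
#' stimulus-locked rate and differ only in Poisson draws.
#'
#' @param unit One row of a [make_units()] tibble (or an equivalent list
#'   with `unit_id`, `target_layer`, `true_trf`, `gain`, `baseline_rate`).
#' @param stacks Named list of `feature_stack`s, one per stimulus id in the
#'   schedule (a single stack is accepted for a one-stimulus schedule).
#' @param schedule A `stim_schedule`.
#' @param bin_width Bin width in seconds (0.05 or 0.02 typically).
#' @param seed Integer seed for the Poisson draws.
#' @return A `response_set` containing this unit's counts.
#' @export
simulate_unit_responses <- function(unit, stacks, schedule,
                                    bin_width = 0.05, seed = 1L) {
  stopifnot(inherits(schedule, "stim_schedule"), bin_width > 0)
  if (inherits(stacks, "feature_stack")) {
    if (nrow(schedule$stimuli) != 1L) {
      abort("a single feature_stack requires a single-stimulus schedule")
    }
    stacks <- setNames(list(stacks), schedule$stimuli$stimulus_id)
  }
  unit <- as_unit_row(unit)
  check_stack_ids(stacks, schedule)
  if (unit$target_layer > stacks[[1]]$L) {
    abort("unit target_layer exceeds the stack depth")
  }
  feats <- binned_layer_features(stacks, schedule, bin_width,
                                 layers = unit$target_layer)
  rates <- unit_bin_rates(unit, feats, layer = unit$target_layer)
  draw_counts(list(rates), schedule, bin_width, unit$unit_id, seed)
}

as_unit_row <- function(unit) {
  if (is.data.frame(unit)) {
    stopifnot(nrow(unit) == 1L)
    unit <- as.list(unit)
    unit$true_trf <- unit$true_trf[[1]]
  }
  stopifnot(unit$gain >= 0, unit$baseline_rate >= 0)
  unit
}

check_stack_ids <- function(stacks, schedule) {
  missing <- setdiff(schedule$stimuli$stimulus_id, names(stacks))
  if (length(missing)) {
    abort(paste0("no feature stack for stimulus: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

# resample the requested layers of every stimulus to the bin rate and
# trim/pad to the schedule's bin count; returns feats[[stim]][[layer]]
binned_layer_features <- function(stacks, schedule, bin_width,
                                  layers = NULL) {
  bins <- schedule_bins(schedule, bin_width)
  bin_rate <- 1 / bin_width
  if (is.null(layers)) layers <- seq_len(stacks[[1]]$L)
  out <- lapply(schedule$stimuli$stimulus_id, function(sid) {
    st <- stacks[[sid]]
    per_layer <- vector("list", st$L)
    for (l in layers) {
      fm <- resample_features(st$layers[[l]], bin_rate)
      per_layer[[l]] <- fit_length(fm_values(fm), bins[[sid]])
    }
    per_layer
  })
  names(out) <- schedule$stimuli$stimulus_id
  out
}

fit_length <- function(x, n) {
  if (nrow(x) >= n) return(x[seq_len(n), , drop = FALSE])
  rbind(x, matrix(rep(x[nrow(x), ], n - nrow(x)),
                  nrow = n - nrow(x), byrow = TRUE))
}

# spikes/s per bin for one unit over every stimulus
unit_bin_rates <- function(unit, feats, layer) {
  w <- as.vector(unit$true_trf)
  n_lags <- ncol(unit$true_trf)
  lapply(feats, function(per_layer) {
    x <- per_layer[[layer]]
    if (ncol(x) != nrow(unit$true_trf)) {
      abort("true_trf dimensionality does not match the target layer")
    }
    drive <- lag_design_matrix(x, n_lags) %*% w
    unit$baseline_rate + unit$gain * pmax(as.numeric(drive), 0)
  })
}

# rates_by_unit: list over units of (list over stimulus of rate vectors)
draw_counts <- function(rates_by_unit, schedule, bin_width, unit_ids, seed) {
  withr_seed(seed)
  counts <- vector("list", nrow(schedule$order))
  for (p in seq_len(nrow(schedule$order))) {
    sid <- schedule$order$stimulus_id[p]
    m <- vapply(rates_by_unit,
                function(r) rpois(length(r[[sid]]), r[[sid]] * bin_width),
                integer(length(rates_by_unit[[1]][[sid]])))
    counts[[p]] <- matrix(t(m), nrow = length(rates_by_unit),
                          dimnames = list(unit_ids, NULL))
  }
  structure(list(counts = counts, schedule = schedule,
                 bin_width = bin_width, unit_ids = unit_ids),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("<response_set> %d units x %d presentations @ %g-ms bins\n",
              length(x$unit_ids), length(x$counts), 1000 * x$bin_width))
  invisible(x)
}

#' Per-stimulus repeat responses for one unit
#'
#' @param responses A `response_set`.
#' @param unit_id One unit id.
#' @param stimuli Stimulus ids to extract (default: the repeat set).
#' @return Named list of trials x bins integer matrices, trials ordered by
#'   repeat index.
#' @export
repeat_responses <- function(responses, unit_id,
                             stimuli = repeat_set(responses$schedule)) {
  stopifnot(inherits(responses, "response_set"))
  ui <- match(unit_id, responses$unit_ids)
  if (is.na(ui)) abort("unknown unit_id: ", unit_id)
  ord <- responses$schedule$order
  out <- lapply(stimuli, function(sid) {
    pres <- which(ord$stimulus_id == sid)
    pres <- pres[order(ord$repeat_index[pres])]
    do.call(rbind, lapply(pres, function(p) responses$counts[[p]][ui, ]))
  })
  names(out) <- stimuli
  out
}

#' Simulate a full synthetic session
#'
#' Generates a stimulus schedule, a base feature process, a feature
#' hierarchy (shared weights across stimuli, centered per dimension across
#' the session), a ground-truth unit population whose drives are calibrated
#' to unit variance, and Poisson spike counts — everything the encoding
#' pipeline consumes, with known ground truth.
#'
#' The base features are a broadband smoothed-noise process at `base_rate`;
#' `base_bandwidth` low-passes them first, which restricts all stimulus-
#' locked structure to below that frequency (used by the time-scale
#' analysis validation).
#'
#' @param n_single,n_repeat_stimuli,n_repeats,duration_mean,duration_jitter
#'   Schedule parameters, as in [make_schedule()].
#' @param n_units Number of units.
#' @param n_layers,strides,layer_dims,kernel_width Hierarchy parameters, as
#'   in [synth_feature_hierarchy()].
#' @param mode Weight regime of the generating hierarchy.
#' @param bin_width Spike-count bin width, seconds.
#' @param base_rate Base feature rate, Hz.
#' @param base_bandwidth Low-pass cutoff for the base process, Hz
#'   (`Inf` = broadband).
#' @param window TRF window of the ground-truth readout, seconds.
#' @param seed Integer seed controlling every draw.
#' @param ... Passed to [make_units()].
#' @return A `sim_session`: list with `schedule`, `stacks` (per-stimulus
#'   `feature_stack`s sharing weights), `units`, `responses`
#'   (`response_set`), `bin_width`, `seed`.
#' @export
simulate_session <- function(n_single = 40, n_repeat_stimuli = 10,
                             n_repeats = 11, duration_mean = 1.6,
                             duration_jitter = 0, n_units = 20,
                             n_layers = 4, strides = c(1, 1, 2, 2),
                             layer_dims = 6, kernel_width = 5L,
                             mode = "trained", bin_width = 0.05,
                             base_rate = 100, base_bandwidth = Inf,
                             window = 0.25, seed = 1L, ...) {
  schedule <- make_schedule(n_single, n_repeat_stimuli, n_repeats,
                            duration_mean, duration_jitter,
                            seed = seed_stream(seed, 1))
  layer_dims <- rep_len(as.integer(layer_dims), n_layers)
  weights <- make_hierarchy_weights(layer_dims, n_layers, kernel_width,
                                    mode, seed_stream(seed, 2))
  stacks <- build_session_stacks(schedule, weights, strides, layer_dims[1],
                                 base_rate, base_bandwidth, mode,
                                 kernel_width, seed)
  bin_rate <- 1 / bin_width
  n_lags <- round_half_up(window * bin_rate)
  units <- make_units(n_units, n_layers, layer_dims, n_lags = n_lags,
                      seed = seed_stream(seed, 4), ...)
  feats <- binned_layer_features(stacks, schedule, bin_width)
  units <- calibrate_units(units, feats)
  rates <- lapply(seq_len(n_units), function(i) {
    u <- as_unit_row(units[i, ])
    unit_bin_rates(u, feats, u$target_layer)
  })
  responses <- draw_counts(rates, schedule, bin_width, units$unit_id,
                           seed_stream(seed, 5))
  structure(list(schedule = schedule, stacks = stacks, units = units,
                 responses = responses, bin_width = bin_width,
                 seed = seed),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf(
    "<sim_session> %d stimuli, %d units, L=%d layers, %g-ms bins (seed %d)\n",
    nrow(x$schedule$stimuli), nrow(x$units), x$stacks[[1]]$L,
    1000 * x$bin_width, x$seed))
  invisible(x)
}

build_session_stacks <- function(schedule, weights, strides, base_dims,
                                 base_rate, base_bandwidth, mode,
                                 kernel_width, seed) {
  ids <- schedule$stimuli$stimulus_id
  stacks <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    n <- max(2L, as.integer(round(schedule$stimuli$duration[i] * base_rate)))
    withr_seed(seed_stream(seed, 3) + i)
    base <- matrix(rnorm(n * base_dims), n, base_dims)
    base <- apply(base, 2, smooth_ma, k = 3L)     # mild smoothing
    base <- matrix(base, ncol = base_dims)
    base <- sweep(base, 2, colMeans(base))
    base <- sweep(base, 2, pmax(apply(base, 2, sd), 1e-12), `/`)
    fm <- feature_matrix(base, base_rate)
    # exact band-limiting: the time-scale analysis needs drive with no
    # energy at all above the stated bandwidth, which an IIR transition
    # band cannot deliver
    if (is.finite(base_bandwidth)) {
      fm <- brickwall_lowpass(fm, base_bandwidth)
    }
    stacks[[i]] <- synth_feature_hierarchy(
      fm, length(strides), strides, mode = mode,
      kernel_width = kernel_width, weights = weights)
  }
  names(stacks) <- ids
  center_stacks(stacks)
}

# subtract the session-wide per-dimension mean from every layer, so linear
# drives of any layer are zero-mean by construction
center_stacks <- function(stacks) {
  L <- stacks[[1]]$L
  for (l in seq_len(L)) {
    mats <- lapply(stacks, function(s) fm_values(s$layers[[l]]))
    mu <- colMeans(do.call(rbind, mats))
    for (i in seq_along(stacks)) {
      fm <- stacks[[i]]$layers[[l]]
      stacks[[i]]$layers[[l]] <- feature_matrix(
        sweep(fm_values(fm), 2, mu), sampling_rate(fm))
    }
  }
  stacks
}

# scale each unit's true TRF so its (pre-rectification) drive has unit
# standard deviation over the whole session; gain is then in spikes/s
calibrate_units <- function(units, feats) {
  for (i in seq_len(nrow(units))) {
    u <- as_unit_row(units[i, ])
    w <- as.vector(u$true_trf)
    n_lags <- ncol(u$true_trf)
    drives <- unlist(lapply(feats, function(per_layer) {
      as.numeric(lag_design_matrix(per_layer[[u$target_layer]], n_lags) %*% w)
    }), use.names = FALSE)
    s <- sd(drives)
    if (s > 0) units$true_trf[[i]] <- u$true_trf / s
  }
  units
}

# zero every DFT bin above the cutoff; used only by the generator, where
# exact band-limiting (not a realizable filter) is the point
brickwall_lowpass <- function(fm, cutoff) {
  rate <- sampling_rate(fm)
  x <- fm_values(fm)
  n <- nrow(x)
  freqs <- (seq_len(n) - 1) * rate / n
  freqs <- pmin(freqs, rate - freqs)          # two-sided spectrum
  keep <- freqs <= cutoff
  y <- apply(x, 2, function(col) Re(fft(fft(col) * keep, inverse = TRUE)) / n)
  feature_matrix(matrix(y, ncol = ncol(x)), rate)
}

# distinct deterministic seeds per pipeline stage, kept within 32-bit range
seed_stream <- function(seed, k) {
  (as.integer(seed) * 1000L + as.integer(k)) %% 2147483647L
}

round_half_up <- function(x) floor(x + 0.5)
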