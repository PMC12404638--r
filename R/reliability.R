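#' Sample one pair of concatenated repeat-response sequences
#'
#' For each repeat stimulus, two distinct trials are drawn at random; the
#' first of each pair is concatenated into a long sequence `U` and the
#' second into `V`, both in the same seeded random stimulus order. With 10
#' repeat sentences of ~1.6 s at 50-ms bins, `U` and `V` are ~320 samples
#' long; with 11 vocalizations of ~1 s, ~220 samples.
#'
#' @param repeat_responses Named list of trials x bins matrices, one per
#'   repeat stimulus (see [repeat_responses()]); every stimulus needs at
#'   least 2 trials.
#' @param seed Integer seed.
#' @return List with numeric vectors `U` and `V` of equal length and
#'   `stimulus_order`.
#' @export
sample_pair_sequences <- function(repeat_responses, seed = 1L) {
  check_repeats(repeat_responses)
  withr_seed(seed)
  M <- length(repeat_responses)
  ord <- sample.int(M)
  pieces <- lapply(repeat_responses[ord], function(y) {
    i <- sample.int(nrow(y), 1L)
    j <- sample.int(nrow(y) - 1L, 1L)
    if (j >= i) j <- j + 1L
    list(u = y[i, ], v = y[j, ])
  })
  list(U = unlist(lapply(pieces, `[[`, "u"), use.names = FALSE),
       V = unlist(lapply(pieces, `[[`, "v"), use.names = FALSE),
       stimulus_order = names(repeat_responses)[ord])
}

check_repeats <- function(repeat_responses) {
  stopifnot(is.list(repeat_responses), length(repeat_responses) >= 1)
  n_tr <- vapply(repeat_responses, nrow, integer(1))
  if (any(n_tr < 2)) {
    abort(paste0("every repeat stimulus needs >= 2 trials; offending: ",
                 paste(names(repeat_responses)[n_tr < 2], collapse = ", ")))
  }
  invisible(TRUE)
}

#' Circular half-length shift (the null transform)
#'
#' Rotates a sequence by half its length: `output[i] = V[(i + floor(n/2))
#' mod n]`. The marginal histogram is preserved exactly while any temporal
#' alignment with a paired sequence is destroyed — the surrogate used to
#' build the null distribution of trial-to-trial correlations.
#'
#' @param v Numeric vector, length >= 2.
#' @return The rotated vector.
#' @examples
#' null_transform(c(1, 2, 3, 4))  # 3 4 1 2
#' @export
null_transform <- function(v) {
  n <- length(v)
  stopifnot(n >= 2)
  h <- n %/% 2L
  v[((seq_len(n) - 1L + h) %% n) + 1L]
}

#' True and null trial-to-trial correlation distributions
#'
#' Repeats the pair-sampling procedure `R` times: each resample draws a
#' distinct trial pair per repeat stimulus, concatenates both members in a
#' shared random stimulus order, and computes the Pearson correlation of
#' `(U, V)` (true) and of `(U, circularly shifted V)` (null). Resamples in
#' which either sequence is constant have an undefined correlation; these
#' are excluded and counted, not set to zero.
#'
#' The default resample count in full analyses is 100,000; smaller `R`
#' trades Monte-Carlo precision for speed.
#'
#' @inheritParams sample_pair_sequences
#' @param R Number of resamples, >= 1.
#' @return List of two `corr_dist` objects, `true` and `null`; each has
#'   `values` (defined correlations), `kind`, `R`, and `n_excluded`.
#' @export
reliability_distributions <- function(repeat_responses, R = 10000L,
                                      seed = 1L) {
  check_repeats(repeat_responses)
  stopifnot(R >= 1)
  withr_seed(seed)
  M <- length(repeat_responses)
  bins <- vapply(repeat_responses, ncol, integer(1))
  n_trials <- vapply(repeat_responses, nrow, integer(1))
  n <- sum(bins)

  # flatten: stimulus s, trial i occupies offsets[s] + (i-1)*bins[s] + 1..bins[s]
  ylong <- unlist(lapply(repeat_responses, function(y) as.vector(t(y))),
                  use.names = FALSE)
  offsets <- c(0L, cumsum(n_trials * bins))[seq_len(M)]

  # trial pairs: i and j distinct, per resample x stimulus
  i_mat <- vapply(n_trials, function(nt) sample.int(nt, R, replace = TRUE),
                  integer(R))
  j_mat <- vapply(n_trials, function(nt) sample.int(nt - 1L, R, replace = TRUE),
                  integer(R))
  j_mat <- j_mat + (j_mat >= i_mat)

  # shared random stimulus order per resample; column r = order of resample r
  perms_mr <- matrix(vapply(seq_len(R), function(r) sample.int(M),
                            integer(M)), nrow = M)

  idx_from <- function(trial_mat) {
    # trial chosen for the stimulus at position k of resample r (M x R)
    sel <- matrix(trial_mat[cbind(rep(seq_len(R), each = M),
                                  as.vector(perms_mr))], nrow = M)
    lens <- matrix(bins[perms_mr], nrow = M)
    starts <- matrix(offsets[perms_mr], nrow = M) + (sel - 1L) * lens + 1L
    sequence(as.vector(lens), from = as.vector(starts))
  }
  U <- matrix(ylong[idx_from(i_mat)], nrow = R, byrow = TRUE)
  V <- matrix(ylong[idx_from(j_mat)], nrow = R, byrow = TRUE)
  h <- n %/% 2L
  Vs <- V[, c((h + 1L):n, seq_len(h)), drop = FALSE]

  r_true <- row_pearson(U, V)
  r_null <- row_pearson(U, Vs)
  make_dist <- function(vals, kind) {
    structure(list(values = vals[!is.na(vals)], kind = kind, R = R,
                   n_excluded = sum(is.na(vals))),
              class = "corr_dist")
  }
  true <- make_dist(r_true, "true")
  null <- make_dist(r_null, "null")
  if (length(true$values) == 0 || length(null$values) == 0) {
    abort("all resampled correlations were undefined (constant sequences)")
  }
  list(true = true, null = null)
}

#' @export
print.corr_dist <- function(x, ...) {
  cat(sprintf("<corr_dist:%s> R=%d, mean=%.3f, sd=%.3f (%d excluded)\n",
              x$kind, x$R, mean(x$values), sd(x$values), x$n_excluded))
  invisible(x)
}

# row-wise Pearson correlation of two equal-shaped matrices; NA where a row
# of either matrix is constant
row_pearson <- function(a, b) {
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  sa <- rowSums(a * a)
  sb <- rowSums(b * b)
  r <- rowSums(a * b) / sqrt(sa * sb)
  r[sa <= 0 | sb <= 0] <- NA_real_
  r
}

#' Rank-sum test for stimulus tuning
#'
#' One-sided Wilcoxon rank-sum (Mann-Whitney) test of whether the true
#' trial-to-trial correlation distribution is greater than its
#' circular-shift null. A unit is "tuned" when p < 0.05. Note the resamples
#' entering the test are themselves correlated (they reuse trials), so the
#' nominal p-value is computed over `R` resamples treated as independent;
#' report `R` alongside p.
#'
#' @param true,null `corr_dist` objects or numeric vectors.
#' @return The one-sided p-value.
#' @export
tuned_test <- function(true, null) {
  tv <- dist_values(true); nv <- dist_values(null)
  stopifnot(length(tv) > 0, length(nv) > 0)
  suppressWarnings(
    wilcox.test(tv, nv, alternative = "greater", exact = FALSE)$p.value)
}

dist_values <- function(x) if (inherits(x, "corr_dist")) x$values else x

#' Well-tuned criterion
#'
#' A unit is well-tuned when it is tuned (rank-sum p < `alpha`) and the
#' means of its true and null distributions are separated by at least
#' `delta` null standard deviations. The boundary is inclusive
#' (gap exactly `delta` passes). The default `delta = 0.5` sits at the
#' elbow of accepted-unit counts versus gap; `delta = 1` is the usual
#' robustness reprise.
#'
#' @inheritParams tuned_test
#' @param delta Gap threshold in null standard deviations.
#' @param alpha Rank-sum level for the tuned component of the criterion.
#' @return Logical scalar.
#' @export
well_tuned <- function(true, null, delta = .encodetrf_defaults$delta,
                       alpha = .encodetrf_defaults$tuned_alpha) {
  tv <- dist_values(true); nv <- dist_values(null)
  s <- sd(nv)
  if (!is.finite(s) || s <= 0) abort("null distribution has zero variance")
  gap <- (mean(tv) - mean(nv)) / s
  gap_at_least(gap, delta) && tuned_test(tv, nv) < alpha
}

# inclusive boundary with a round-off guard, so a gap of exactly
# delta null-SDs passes regardless of floating-point representation
gap_at_least <- function(gap, delta) gap >= delta - 1e-12

#' Noise-ceiling correction of a model-neuron correlation
#'
#' Trial-to-trial variability caps the correlation any noise-free model can
#' achieve. There are two independent noise sources in a trial-to-trial
#' correlation but only one in a model-neuron correlation, so the raw
#' model correlation is divided by the *square root* of the expected
#' correlation between responses to identical stimuli (the "ceiling",
#' estimated as the mean of the true trial-to-trial distribution).
#'
#' @param r_model Raw model-neuron correlation(s).
#' @param ceiling Reliability ceiling(s), the mean true trial-to-trial
#'   correlation.
#' @param floor Ceilings at or below this are uncorrectable: the result is
#'   `NA` (flagged, never clipped).
#' @return Corrected correlation(s); `NA` where the ceiling is at or below
#'   `floor`.
#' @examples
#' noise_correct(0.3, 0.36)  # 0.5
#' @export
noise_correct <- function(r_model, ceiling,
                          floor = .encodetrf_defaults$ceiling_floor) {
  out <- r_model / sqrt(pmax(ceiling, .Machine$double.xmin))
  out[!is.na(ceiling) & ceiling <= floor] <- NA_real_
  out
}

#' Per-unit reliability table for a session
#'
#' Runs [reliability_distributions()] for every unit of a response set and
#' tabulates ceiling, tuning p-value, gap, and well-tuned status — the unit
#' selection table everything downstream filters on.
#'
#' @param responses A `response_set`.
#' @param R Resamples per unit.
#' @param delta,alpha Well-tuned criterion parameters.
#' @param seed Integer seed (one independent stream per unit).
#' @return Tibble: `unit_id`, `ceiling`, `null_mean`, `null_sd`, `gap`,
#'   `tuned_p`, `tuned`, `well_tuned`, `n_excluded`.
#' @export
session_reliability <- function(responses, R = 10000L,
                                delta = .encodetrf_defaults$delta,
                                alpha = .encodetrf_defaults$tuned_alpha,
                                seed = 1L) {
  stopifnot(inherits(responses, "response_set"))
  rows <- lapply(seq_along(responses$unit_ids), function(i) {
    uid <- responses$unit_ids[i]
    rr <- repeat_responses(responses, uid)
    d <- reliability_distributions(rr, R = R, seed = seed_stream(seed, i))
    p <- tuned_test(d$true, d$null)
    ns <- sd(d$null$values)
    gap <- (mean(d$true$values) - mean(d$null$values)) / ns
    tibble::tibble(
      unit_id = uid,
      ceiling = mean(d$true$values),
      null_mean = mean(d$null$values),
      null_sd = ns,
      gap = gap,
      tuned_p = p,
      tuned = p < alpha,
      well_tuned = gap_at_least(gap, delta) && (p < alpha),
      n_excluded = d$true$n_excluded + d$null$n_excluded
    )
  })
  dplyr::bind_rows(rows)
}
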