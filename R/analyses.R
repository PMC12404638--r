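#' Most predictive layer per unit
#'
#' For each unit, finds the hierarchy layer whose TRF achieves the highest
#' noise-corrected correlation and expresses its depth as a fraction of the
#' total depth (1-based layer index over `L`, so the fraction lies in
#' (0, 1]). Ties break to the shallowest layer; units with no defined score
#' at any layer are excluded.
#'
#' @param scores Tibble with columns `unit_id`, `layer`, `corrected_r`
#'   (one hierarchy variant; e.g. `session_scores()` output filtered to
#'   `variant == "trained"`).
#' @param L Total depth; defaults to the largest layer index present.
#' @return Tibble: `unit_id`, `best_layer`, `depth_fraction`.
#' @export
best_layer <- function(scores, L = max(scores$layer, na.rm = TRUE)) {
  stopifnot(all(c("unit_id", "layer", "corrected_r") %in% names(scores)))
  scores |>
    dplyr::filter(!is.na(.data$layer)) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::filter(any(!is.na(.data$corrected_r))) |>
    dplyr::arrange(.data$layer, .by_group = TRUE) |>
    dplyr::summarise(
      best_layer = .data$layer[which.max(.data$corrected_r)],
      .groups = "drop"
    ) |>
    dplyr::mutate(depth_fraction = .data$best_layer / L)
}

#' Layer-preference table with region labels
#'
#' Convenience wrapper joining [best_layer()] results to the unit table's
#' region labels, ready for [hierarchy_compare()] and plotting.
#'
#' @param scores As in [best_layer()].
#' @param units Tibble with `unit_id` and `region` columns (e.g.
#'   `session$units`).
#' @param L Total depth.
#' @return Tibble: `unit_id`, `best_layer`, `depth_fraction`, `region`.
#' @export
layer_preferences <- function(scores, units,
                              L = max(scores$layer, na.rm = TRUE)) {
  best_layer(scores, L) |>
    dplyr::inner_join(units[, c("unit_id", "region")], by = "unit_id")
}

#' Test whether non-primary units prefer deeper layers
#'
#' One-sided Wilcoxon rank-sum test of the hypothesis that best-layer
#' depth fractions are larger for non-primary than for primary units (the
#' "soft hierarchy" signature; pooled across stacks in the headline
#' analysis, per stack in breakdowns).
#'
#' @param depths_primary,depths_non_primary Numeric depth fractions per
#'   group, both nonempty.
#' @return The one-sided p-value (non-primary deeper).
#' @export
hierarchy_compare <- function(depths_primary, depths_non_primary) {
  stopifnot(length(depths_primary) > 0, length(depths_non_primary) > 0)
  suppressWarnings(
    wilcox.test(depths_non_primary, depths_primary,
                alternative = "greater", exact = FALSE)$p.value)
}

#' Time-scale analysis: low-pass sweep of layer features
#'
#' How fine is the temporal structure the readout actually predicts? For
#' each cutoff frequency, the chosen layer's features (already at the bin
#' rate) are zero-phase low-pass filtered, the TRF is refit per unit on the
#' training stimuli, and held-out corrected correlations are recomputed.
#' The best cutoff maximizes the median corrected correlation across
#' units; the "indistinguishable set" contains every cutoff whose paired
#' signed-rank test against the best has p >= `alpha` (plus the best
#' itself). A cutoff at the bin-rate Nyquist leaves the features untouched
#' and so reproduces the unfiltered scores exactly.
#'
#' @param session A `sim_session`, typically at 20-ms bins (50 Hz).
#' @param reliability Reliability table ([session_reliability()]).
#' @param cutoffs Ascending cutoff frequencies in Hz, all at or below the
#'   bin-rate Nyquist.
#' @param layer Hierarchy layer to sweep (default 1, the base).
#' @param units Unit ids (default: well-tuned units).
#' @param alpha Signed-rank level defining indistinguishability.
#' @inheritParams session_scores
#' @return A `timescale_curve`: tibble (`cutoff`, `unit_id`,
#'   `corrected_r`) with attributes `summary` (tibble: cutoff, median_r,
#'   q25, q75), `best_cutoff`, `indistinguishable`.
#' @export
timescale_sweep <- function(session, reliability, cutoffs, layer = 1L,
                            units = NULL, window = 0.25,
                            lambda_grid = default_lambda_grid(),
                            k_folds = 3L,
                            alpha = .encodetrf_defaults$stars_alpha,
                            seed = 1L) {
  stopifnot(inherits(session, "sim_session"), length(cutoffs) >= 1)
  cutoffs <- sort(cutoffs)
  nyq <- 1 / (2 * session$bin_width)
  if (any(cutoffs > nyq + 1e-9)) {
    abort("cutoffs must not exceed the bin-rate Nyquist frequency")
  }
  if (is.null(units)) units <- reliability$unit_id[reliability$well_tuned]
  if (!length(units)) abort("no units selected for the sweep")
  ceilings <- setNames(reliability$ceiling, reliability$unit_id)[units]

  bin_rate <- 1 / session$bin_width
  bins <- schedule_bins(session$schedule, session$bin_width)
  raw <- lapply(session$schedule$stimuli$stimulus_id, function(sid) {
    fm <- resample_features(session$stacks[[sid]]$layers[[layer]], bin_rate)
    feature_matrix(fit_length(fm_values(fm), bins[[sid]]), bin_rate)
  })
  names(raw) <- session$schedule$stimuli$stimulus_id

  per_cutoff <- lapply(cutoffs, function(fc) {
    feats <- lapply(raw, lowpass, cutoff = fc)
    sc <- fit_and_score(session, feats, units, ceilings, window,
                        lambda_grid, k_folds)
    tibble::tibble(cutoff = fc, unit_id = sc$unit_id,
                   corrected_r = sc$corrected_r)
  })
  curve <- dplyr::bind_rows(per_cutoff)

  summary_tbl <- curve |>
    dplyr::group_by(.data$cutoff) |>
    dplyr::summarise(median_r = median(.data$corrected_r, na.rm = TRUE),
                     q25 = quantile(.data$corrected_r, 0.25, na.rm = TRUE),
                     q75 = quantile(.data$corrected_r, 0.75, na.rm = TRUE),
                     .groups = "drop")
  best <- summary_tbl$cutoff[which.max(summary_tbl$median_r)]
  wide <- tidyr::pivot_wider(curve, names_from = "cutoff",
                             values_from = "corrected_r")
  best_col <- wide[[as.character(best)]]
  indist <- vapply(cutoffs, function(fc) {
    if (fc == best) return(TRUE)
    d <- wide[[as.character(fc)]] - best_col
    d <- d[!is.na(d)]
    p <- if (!length(d) || all(d == 0)) 1 else
      suppressWarnings(wilcox.test(d, exact = FALSE)$p.value)
    p >= alpha
  }, logical(1))

  structure(curve, class = c("timescale_curve", class(curve)),
            summary = summary_tbl, best_cutoff = best,
            indistinguishable = cutoffs[indist])
}

#' @export
print.timescale_curve <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<timescale_curve> %d cutoffs, best = %g Hz (indistinguishable: %s)\n",
              nrow(s), attr(x, "best_cutoff"),
              paste(attr(x, "indistinguishable"), collapse = ", ")))
  print(s)
  invisible(x)
}
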