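#' Assemble held-out long sequences for scoring
#'
#' Concatenates the model prediction for every repeat stimulus into one
#' long model sequence (fixed stimulus order), and the recorded responses
#' into one long sequence per repeat index, all in the same order — e.g. 11
#' response sequences for 10 sentences repeated 11 times.
#'
#' @param repeat_responses Named list of trials x bins matrices (see
#'   [repeat_responses()]); every stimulus must have the same trial count.
#' @param predictions Named list of numeric prediction vectors, one per
#'   repeat stimulus, each as long as that stimulus's bin count.
#' @return List with `model` (numeric vector) and `responses` (list of
#'   equally long numeric vectors, one per repeat index).
#' @export
assemble_long_sequences <- function(repeat_responses, predictions) {
  stopifnot(length(repeat_responses) >= 1)
  ids <- names(repeat_responses)
  missing <- setdiff(ids, names(predictions))
  if (length(missing)) {
    abort(paste0("no prediction for stimulus: ", paste(missing, collapse = ", ")))
  }
  n_rep <- vapply(repeat_responses, nrow, integer(1))
  if (length(unique(n_rep)) != 1L) {
    bad <- names(n_rep)[n_rep != n_rep[1]]
    abort(paste0("ragged repeat counts; offending stimulus: ",
                 paste(bad, collapse = ", ")))
  }
  for (sid in ids) {
    if (length(predictions[[sid]]) != ncol(repeat_responses[[sid]])) {
      abort(paste0("prediction length mismatch for stimulus ", sid))
    }
  }
  model <- unlist(predictions[ids], use.names = FALSE)
  responses <- lapply(seq_len(n_rep[1]), function(r) {
    unlist(lapply(repeat_responses[ids], function(y) y[r, ]),
           use.names = FALSE)
  })
  list(model = model, responses = responses)
}

#' Score one (unit, model) pair on the held-out repeat set
#'
#' Pearson-correlates the long model sequence with each per-repeat long
#' response sequence, reports the mean of those correlations, and corrects
#' it by the unit's reliability ceiling ([noise_correct()]).
#'
#' @param model_sequence Numeric model prediction sequence.
#' @param response_sequences List of equally long response sequences (one
#'   per repeat).
#' @param ceiling The unit's reliability ceiling.
#' @param unit_id,model_id Identifiers carried into the output.
#' @return One-row tibble: `unit_id`, `model_id`, `per_repeat_r`
#'   (list-column), `mean_r`, `corrected_r`, `flagged` (constant model
#'   sequence or uncorrectable ceiling).
#' @export
score_unit <- function(model_sequence, response_sequences, ceiling,
                       unit_id = NA_character_, model_id = NA_character_) {
  stopifnot(length(response_sequences) >= 1)
  lens <- lengths(response_sequences)
  stopifnot(all(lens == length(model_sequence)))
  if (sd(model_sequence) == 0) {
    return(tibble::tibble(unit_id = unit_id, model_id = model_id,
                          per_repeat_r = list(rep(NA_real_, length(lens))),
                          mean_r = NA_real_, corrected_r = NA_real_,
                          flagged = TRUE))
  }
  r <- vapply(response_sequences, function(y) {
    if (sd(y) == 0) NA_real_ else cor(model_sequence, y)
  }, numeric(1))
  mean_r <- mean(r, na.rm = TRUE)
  corrected <- noise_correct(mean_r, ceiling)
  tibble::tibble(unit_id = unit_id, model_id = model_id,
                 per_repeat_r = list(unname(r)), mean_r = mean_r,
                 corrected_r = corrected,
                 flagged = is.na(corrected) || all(is.na(r)))
}

#' Paired layer-wise model comparisons with FDR control
#'
#' For each layer of a model, two paired Wilcoxon signed-rank tests across
#' units: trained versus its untrained counterpart, and trained versus the
#' STRF baseline — 2 x L tests per model, with the Benjamini-Hochberg
#' correction applied within that family at `alpha` (default 0.01, the
#' usual starred threshold). Tests are two-sided with the direction
#' reported. Units with an undefined score in either member of a pair are
#' dropped pairwise.
#'
#' @param scores Long tibble with columns `unit_id`, `variant` (one of
#'   `"trained"`, `"untrained"`, `"strf"`), `layer` (`NA` for the STRF),
#'   `corrected_r`.
#' @param alpha BH level for the starred decisions.
#' @return Tibble: `layer`, `comparison`, `n`, `p_value`, `direction`
#'   (sign of the median paired difference), `significant` (BH-adjusted
#'   decision at `alpha`).
#' @export
compare_models <- function(scores, alpha = .encodetrf_defaults$stars_alpha) {
  needed <- c("unit_id", "variant", "layer", "corrected_r")
  stopifnot(all(needed %in% names(scores)))
  layers <- sort(unique(scores$layer[scores$variant == "trained"]))
  strf <- scores[scores$variant == "strf", c("unit_id", "corrected_r")]
  rows <- list()
  for (l in layers) {
    tr <- scores[scores$variant == "trained" & scores$layer == l,
                 c("unit_id", "corrected_r")]
    un <- scores[scores$variant == "untrained" & scores$layer == l,
                 c("unit_id", "corrected_r")]
    rows[[length(rows) + 1L]] <-
      paired_signed_rank(tr, un, l, "trained_vs_untrained")
    rows[[length(rows) + 1L]] <-
      paired_signed_rank(tr, strf, l, "trained_vs_strf")
  }
  out <- dplyr::bind_rows(rows)
  out$significant <- bh_significant(out$p_value, alpha)
  out
}

#' Benjamini-Hochberg step-up decisions
#'
#' Rejections at false-discovery-rate level `alpha` within one family of
#' tests (a thin wrapper over `p.adjust(method = "BH")`, kept as the single
#' decision point for every comparison family in the package).
#'
#' @param p Raw p-values (NAs allowed, never rejected).
#' @param alpha FDR level.
#' @return Logical vector of rejection decisions.
#' @export
bh_significant <- function(p, alpha = .encodetrf_defaults$stars_alpha) {
  out <- p.adjust(p, method = "BH") < alpha
  out[is.na(out)] <- FALSE
  out
}

paired_signed_rank <- function(a, b, layer, comparison) {
  if (!nrow(b)) {
    return(tibble::tibble(layer = layer, comparison = comparison, n = 0L,
                          p_value = NA_real_, direction = NA_real_))
  }
  m <- dplyr::inner_join(a, b, by = "unit_id", suffix = c("_a", "_b"))
  if (nrow(m) < nrow(a) || nrow(m) < nrow(b)) {
    extra <- union(setdiff(a$unit_id, b$unit_id), setdiff(b$unit_id, a$unit_id))
    abort(paste0("unpaired units in ", comparison, " at layer ", layer, ": ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  ok <- !is.na(m$corrected_r_a) & !is.na(m$corrected_r_b)
  d <- m$corrected_r_a[ok] - m$corrected_r_b[ok]
  p <- if (length(d) == 0 || all(d == 0)) 1 else
    suppressWarnings(wilcox.test(d, exact = FALSE)$p.value)
  tibble::tibble(layer = layer, comparison = comparison, n = sum(ok),
                 p_value = p, direction = sign(median(d)))
}

#' Model-to-STRF correlation ratio
#'
#' The alternative report to noise correction: each model-neuron
#' correlation divided by the same unit's STRF-neuron correlation. The
#' common ceiling normalizer cancels, so the ratio is identical whether
#' computed from corrected or raw correlations; the STRF's own ratio is 1.
#'
#' @param r_model Model correlation(s) (corrected or raw, consistently).
#' @param r_strf The same unit's STRF correlation(s) on the same scale.
#' @return `r_model / r_strf`; `NA` (flagged) where the denominator is 0.
#' @export
correlation_ratio <- function(r_model, r_strf) {
  out <- r_model / r_strf
  out[!is.na(r_strf) & r_strf == 0] <- NA_real_
  out
}
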