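#' Fit and score every layer of a session's hierarchy
#'
#' The full encoding loop for a synthetic (or imported) session: TRFs are
#' fit per unit and per layer on the once-presented stimuli and scored on
#' the held-out repeat set via concatenated long sequences, with noise
#' correction by each unit's reliability ceiling. Optionally repeats the
#' loop on a perturbed (untrained or permuted) hierarchy and on an STRF
#' baseline whose input features default to the session's base (frontend)
#' features.
#'
#' One design matrix is shared by every unit at a given layer, so the
#' cross-validated ridge path is solved for all units at once.
#'
#' @param session A `sim_session`.
#' @param reliability Per-unit reliability table from
#'   [session_reliability()]; only rows with `well_tuned` are scored unless
#'   `units` overrides the selection.
#' @param variants Character subset of `c("trained", "untrained",
#'   "permuted")`: which hierarchies to score. `"trained"` uses the
#'   session's own stacks; the others perturb them with
#'   [perturb_hierarchy()].
#' @param include_strf Score the STRF baseline too (default TRUE).
#' @param strf_features Named list of `feature_matrix` objects per stimulus
#'   for the STRF frontend; defaults to layer 1 (the base features) of the
#'   session stacks, the synthetic stand-in for the stimulus amplitude
#'   spectrum.
#' @param units Unit ids to score (default: well-tuned units).
#' @param window TRF window in seconds.
#' @param lambda_grid,k_folds Passed to the ridge fit.
#' @param seed Integer seed (perturbation draws).
#' @return Long tibble: `unit_id`, `variant`, `layer` (`NA` for the STRF),
#'   `model_id`, `mean_r`, `corrected_r`, `flagged`.
#' @export
session_scores <- function(session, reliability,
                           variants = c("trained", "untrained"),
                           include_strf = TRUE, strf_features = NULL,
                           units = NULL, window = 0.25,
                           lambda_grid = default_lambda_grid(),
                           k_folds = 3L, seed = 1L) {
  stopifnot(inherits(session, "sim_session"))
  variants <- match.arg(variants, c("trained", "untrained", "permuted"),
                        several.ok = TRUE)
  if (is.null(units)) units <- reliability$unit_id[reliability$well_tuned]
  if (!length(units)) abort("no units selected for scoring")
  ceilings <- setNames(reliability$ceiling, reliability$unit_id)[units]

  out <- list()
  for (v in variants) {
    stacks <- session_variant_stacks(session, v, seed)
    for (l in seq_len(stacks[[1]]$L)) {
      feats <- stack_layer_features(stacks, l)
      sc <- fit_and_score(session, feats, units, ceilings, window,
                          lambda_grid, k_folds)
      sc$variant <- v
      sc$layer <- l
      sc$model_id <- paste0(v, "_L", l)
      out[[length(out) + 1L]] <- sc
    }
  }
  if (include_strf) {
    if (is.null(strf_features)) {
      strf_features <- stack_layer_features(session$stacks, 1L)
    }
    sc <- fit_and_score(session, strf_features, units, ceilings, window,
                        lambda_grid, k_folds)
    sc$variant <- "strf"
    sc$layer <- NA_integer_
    sc$model_id <- "strf"
    out[[length(out) + 1L]] <- sc
  }
  dplyr::bind_rows(out)[, c("unit_id", "variant", "layer", "model_id",
                            "mean_r", "corrected_r", "flagged")]
}

session_variant_stacks <- function(session, variant, seed) {
  if (variant == "trained") return(session$stacks)
  mode <- if (variant == "untrained") "reinitialize" else "permute"
  # one shared perturbation seed: all stimuli keep the same weights
  pw <- perturb_weights(session$stacks[[1]]$weights, mode,
                        seed_stream(seed, 91),
                        kernel_width = session$stacks[[1]]$kernel_width)
  stacks <- lapply(session$stacks, function(st) {
    out <- st
    out$weights <- pw
    out$layers <- apply_hierarchy(st$base, pw, st$strides)
    out
  })
  center_stacks(stacks)
}

stack_layer_features <- function(stacks, layer) {
  lapply(stacks, function(st) st$layers[[layer]])
}

# fit TRFs for all requested units on the training stimuli of a session
# and score them on the repeat set
fit_and_score <- function(session, feats_by_stim, units, ceilings, window,
                          lambda_grid, k_folds) {
  sch <- session$schedule
  bin_rate <- 1 / session$bin_width
  spec <- lag_spec(window, bin_rate)
  bins <- schedule_bins(sch, session$bin_width)

  binned <- lapply(sch$stimuli$stimulus_id, function(sid) {
    fm <- resample_features(feats_by_stim[[sid]], bin_rate)
    feature_matrix(fit_length(fm_values(fm), bins[[sid]]), bin_rate)
  })
  names(binned) <- sch$stimuli$stimulus_id

  train_ids <- sch$stimuli$stimulus_id[sch$stimuli$n_repeats == 1]
  test_ids <- repeat_set(sch)
  if (!length(train_ids)) abort("session has no once-presented training stimuli")
  design <- build_lagged_design(binned[train_ids], spec)
  Y <- training_counts(session, train_ids, units)
  fit <- fit_trf_multi(design, Y, lambda_grid, k_folds)

  preds <- lapply(test_ids, function(sid) {
    build_lagged_design(binned[[sid]], spec)
  })
  names(preds) <- test_ids

  rows <- lapply(seq_along(units), function(j) {
    uid <- units[j]
    pred_u <- lapply(preds, function(X)
      as.numeric(X %*% fit$weights[, j] + fit$intercept[j]))
    rr <- repeat_responses(session$responses, uid, test_ids)
    seqs <- assemble_long_sequences(rr, pred_u)
    score_unit(seqs$model, seqs$responses, ceilings[[uid]], unit_id = uid)
  })
  dplyr::bind_rows(rows)
}

# units x bins count matrix over the single presentations of train_ids,
# assembled in the canonical stimulus order; returns bins x units
training_counts <- function(session, train_ids, units) {
  ord <- session$responses$schedule$order
  ui <- match(units, session$responses$unit_ids)
  blocks <- lapply(train_ids, function(sid) {
    p <- which(ord$stimulus_id == sid)[1]
    t(session$responses$counts[[p]][ui, , drop = FALSE])
  })
  do.call(rbind, blocks)
}

#' Prediction of the true firing rate (oracle model) for one unit
#'
#' Returns the noiseless per-bin expected counts of a ground-truth unit on
#' the repeat set — the best possible model sequence, used to check that
#' noise-corrected correlations of a perfect model approach 1.
#'
#' @param session A `sim_session`.
#' @param unit_id One unit id.
#' @return Named list of numeric expected-count vectors per repeat
#'   stimulus.
#' @export
true_rate_predictions <- function(session, unit_id) {
  u <- as_unit_row(session$units[session$units$unit_id == unit_id, ])
  feats <- binned_layer_features(session$stacks, session$schedule,
                                 session$bin_width,
                                 layers = u$target_layer)
  rates <- unit_bin_rates(u, feats, u$target_layer)
  lapply(rates[repeat_set(session$schedule)],
         function(r) r * session$bin_width)
}
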