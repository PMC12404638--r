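#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end run, as a named list that
#' round-trips through YAML/JSON. Fields mirror the stage functions:
#' schedule (`n_single`, `n_repeat_stimuli`, `n_repeats`, durations),
#' hierarchy (`n_layers`, `strides`, `layer_dims`, `mode`), population
#' (`n_units`, `prop_primary`, `crossover`, gain/baseline ranges),
#' analysis (`bin_width`, `window`, `R`, `delta`, `tuned_alpha`,
#' `stars_alpha`, `lambda_n`, `k_folds`, `variants`, `include_strf`), and
#' `seed`.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    n_single = 40, n_repeat_stimuli = 10, n_repeats = 11,
    duration_mean = 1.6, duration_jitter = 0,
    n_layers = 4, strides = c(1, 1, 2, 2), layer_dims = 6,
    mode = "trained",
    n_units = 20, prop_primary = 0.5, crossover = 0.25,
    gain_range = c(20, 60), baseline_range = c(2, 10),
    bin_width = 0.05, window = 0.25,
    R = 2000, delta = 0.5, tuned_alpha = 0.05, stars_alpha = 0.01,
    lambda_n = 21, k_folds = 3,
    variants = c("trained", "untrained"), include_strf = TRUE,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  }
  structure(modifyList(cfg, over), class = c("run_config", "list"))
}

#' Read / write a pipeline configuration
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: a
#'   `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full pipeline on a synthetic session
#'
#' Executes simulate -> reliability -> fit (all layers of every requested
#' hierarchy variant, plus the STRF baseline) -> evaluate -> population
#' analyses, writing all tables when `out_dir` is given. Each stochastic
#' stage derives its own seed from `cfg$seed`, so two runs of the same
#' config are identical file-for-file.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List of class `run_report`: `session`, `reliability`, `scores`,
#'   `comparisons`, `preferences`, `hierarchy_p`, `counts` (units at each
#'   selection stage), `config`.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  session <- with_stage("simulate", simulate_session(
    n_single = cfg$n_single, n_repeat_stimuli = cfg$n_repeat_stimuli,
    n_repeats = cfg$n_repeats, duration_mean = cfg$duration_mean,
    duration_jitter = cfg$duration_jitter, n_units = cfg$n_units,
    n_layers = cfg$n_layers, strides = cfg$strides,
    layer_dims = cfg$layer_dims, mode = cfg$mode,
    bin_width = cfg$bin_width, window = cfg$window, seed = cfg$seed,
    prop_primary = cfg$prop_primary, crossover = cfg$crossover,
    gain_range = cfg$gain_range, baseline_range = cfg$baseline_range))
  reliab <- with_stage("reliability", session_reliability(
    session$responses, R = cfg$R, delta = cfg$delta,
    alpha = cfg$tuned_alpha, seed = seed_stream(cfg$seed, 21)))
  scores <- with_stage("fit+evaluate", session_scores(
    session, reliab, variants = cfg$variants,
    include_strf = cfg$include_strf, window = cfg$window,
    lambda_grid = default_lambda_grid(cfg$lambda_n),
    k_folds = cfg$k_folds, seed = seed_stream(cfg$seed, 22)))
  comparisons <- with_stage("compare", {
    if (all(c("trained", "untrained") %in% cfg$variants) &&
        cfg$include_strf) {
      compare_models(scores, alpha = cfg$stars_alpha)
    } else NULL
  })
  prefs <- with_stage("analyze", layer_preferences(
    dplyr::filter(scores, .data$variant == "trained"), session$units,
    L = cfg$n_layers))
  hierarchy_p <- if (length(unique(prefs$region)) == 2) {
    hierarchy_compare(prefs$depth_fraction[prefs$region == "primary"],
                      prefs$depth_fraction[prefs$region == "non-primary"])
  } else NA_real_
  counts <- list(total = nrow(reliab), tuned = sum(reliab$tuned),
                 well_tuned = sum(reliab$well_tuned),
                 scored = length(unique(scores$unit_id)))
  report <- structure(list(session = session, reliability = reliab,
                           scores = scores, comparisons = comparisons,
                           preferences = prefs, hierarchy_p = hierarchy_p,
                           counts = counts, config = cfg),
                      class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$reliability,
                   file.path(out_dir, "reliability.csv"), row.names = FALSE)
  sc <- report$scores
  sc$per_repeat_r <- NULL
  utils::write.csv(sc, file.path(out_dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(report$preferences,
                   file.path(out_dir, "layer_preferences.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(report$config), counts = report$counts,
         hierarchy_p = report$hierarchy_p,
         comparisons = report$comparisons),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  units: %d total, %d tuned, %d well-tuned, %d scored\n",
              x$counts$total, x$counts$tuned, x$counts$well_tuned,
              x$counts$scored))
  cat(sprintf("  hierarchy (non-primary deeper) p = %.3g\n", x$hierarchy_p))
  invisible(x)
}
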