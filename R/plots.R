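#' Plot a time-scale sweep
#'
#' Median corrected correlation (line) and interquartile range (ribbon) as
#' a function of low-pass cutoff; the best cutoff is starred and
#' indistinguishable cutoffs are dotted.
#'
#' @param object A `timescale_curve` from [timescale_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.timescale_curve <- function(object, ...) {
  s <- attr(object, "summary")
  best <- attr(object, "best_cutoff")
  indist <- attr(object, "indistinguishable")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$cutoff, y = .data$median_r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = s[s$cutoff %in% indist, ], shape = 16) +
    ggplot2::geom_point(data = s[s$cutoff == best, ], shape = 8, size = 3,
                        colour = "red") +
    ggplot2::labs(x = "low-pass cutoff (Hz)",
                  y = "noise-corrected correlation",
                  title = "Prediction time scale") +
    ggplot2::theme_minimal()
}

#' Plot layer-preference distributions by region
#'
#' Normalized-depth histograms with kernel density overlays for primary
#' versus non-primary units.
#'
#' @param preferences Output of [layer_preferences()].
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_layer_preferences <- function(preferences, bins = 10) {
  ggplot2::ggplot(preferences,
                  ggplot2::aes(x = .data$depth_fraction,
                               fill = .data$region,
                               colour = .data$region)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, position = "identity",
                            alpha = 0.35) +
    ggplot2::geom_density(fill = NA) +
    ggplot2::labs(x = "depth of most predictive layer (fraction)",
                  y = "density", title = "Layer preference by region") +
    ggplot2::theme_minimal()
}

#' Plot true versus null trial-to-trial correlation distributions
#'
#' @param true,null `corr_dist` objects from
#'   [reliability_distributions()].
#' @return A ggplot object with the two distributions and their means.
#' @export
plot_reliability <- function(true, null) {
  df <- dplyr::bind_rows(
    tibble::tibble(kind = "true", r = dist_values(true)),
    tibble::tibble(kind = "null", r = dist_values(null)))
  mu <- df |> dplyr::group_by(.data$kind) |>
    dplyr::summarise(m = mean(.data$r), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, fill = .data$kind)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, position = "identity", alpha = 0.4) +
    ggplot2::geom_vline(data = mu,
                        ggplot2::aes(xintercept = .data$m,
                                     colour = .data$kind),
                        linetype = "dashed") +
    ggplot2::labs(x = "trial-to-trial correlation", y = "density",
                  title = "Reliability: true vs circular-shift null") +
    ggplot2::theme_minimal()
}

#' Plot a fitted TRF as a lag x dimension heatmap
#'
#' @param object A `trf_model`.
#' @param n_dims Feature dimensionality (weights are reshaped to
#'   dims x lags); inferred only if supplied.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trf_model <- function(object, n_dims = NULL, ...) {
  w <- object$weights
  if (is.null(n_dims)) n_dims <- 1L
  n_lags <- length(w) / n_dims
  if (n_lags != round(n_lags)) abort("n_dims does not divide the weight count")
  df <- tidyr::expand_grid(lag = seq_len(n_lags), dim = seq_len(n_dims))
  df$weight <- w[(df$lag - 1L) * n_dims + df$dim]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$dim,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "lag (oldest to newest)", y = "feature dimension",
                  title = sprintf("TRF weights (lambda = %.3g)",
                                  object$lambda)) +
    ggplot2::theme_minimal()
}
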