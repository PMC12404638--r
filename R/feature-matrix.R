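#' Construct a sampled feature matrix
#'
#' The elementary container for any time-varying feature set: cochleagram
#' channels, a hierarchy layer's activations, or synthetic latent features.
#' Rows are time frames at `sampling_rate`; columns are feature dimensions.
#'
#' @param values Numeric matrix (time x dimensions) or vector (one dimension).
#' @param sampling_rate Frames per second, > 0.
#' @return A `feature_matrix` (a matrix with a `sampling_rate` attribute).
#' @export
feature_matrix <- function(values, sampling_rate) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  stopifnot(is.matrix(values), is.numeric(values), sampling_rate > 0)
  if (!all(is.finite(values))) abort("feature values must be finite")
  structure(values, sampling_rate = as.numeric(sampling_rate),
            class = c("feature_matrix", "matrix", "array"))
}

#' @rdname feature_matrix
#' @param x A `feature_matrix`.
#' @export
sampling_rate <- function(x) {
  r <- attr(x, "sampling_rate")
  if (is.null(r)) abort("object has no sampling_rate attribute")
  r
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d frames x %d dims @ %g Hz\n",
              nrow(x), ncol(x), sampling_rate(x)))
  invisible(x)
}

# strip class/attr for plain matrix math
fm_values <- function(x) {
  y <- unclass(x)
  attr(y, "sampling_rate") <- NULL
  y
}
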