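#' Dimensionality reduction by PCA variance thresholding
#'
#' Mean-centered (not variance-standardized) covariance PCA: subtract the
#' column means, eigendecompose the covariance matrix, and retain the
#' minimal number of leading components whose cumulative eigenvalue
#' fraction reaches `variance_fraction`. The "new data set" is the matrix
#' of scores (projections) on the retained components.
#'
#' @param x A `feature_matrix` or numeric matrix (faces in rows).
#' @param variance_fraction Fraction of total variance to retain, in
#'   (0, 1]; the study grid is 0.97, 0.98, 0.99.
#' @return A `pca_selection`: list with `n_components`, `loadings`
#'   (p x k), `explained` (per-component variance fractions),
#'   `cumulative` (cumsum of `explained`), `scores` (n x k transformed
#'   data), `center`, and `variance_fraction`.
#' @examples
#' faces <- generate_dataset(synthetic_config(n_per_class = 12, seed = 1))
#' sel <- pca_select(extract_feature_matrix(faces), 0.99)
#' sel$n_components
#' @export
pca_select <- function(x, variance_fraction = 0.99) {
  if (!is.numeric(variance_fraction) || length(variance_fraction) != 1 ||
      variance_fraction <= 0 || variance_fraction > 1) {
    stop("variance_fraction must be a single value in (0, 1]")
  }
  d <- as_xy(x)
  if (nrow(d$X) < 2) stop("PCA needs at least two rows")
  pc <- prcomp(d$X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  cum <- cumsum(frac)
  # minimal k with cumulative fraction >= threshold (tolerate rounding at 1)
  k <- which(cum >= variance_fraction - 1e-12)[1]
  if (is.na(k)) k <- length(cum)
  structure(list(n_components = as.integer(k),
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = frac,
                 cumulative = cum,
                 scores = pc$x[, seq_len(k), drop = FALSE],
                 center = pc$center,
                 variance_fraction = variance_fraction),
            class = "pca_selection")
}

#' @export
print.pca_selection <- function(x, ...) {
  cat("<pca_selection> ", x$n_components, " components retain ",
      sprintf("%.2f%%", 100 * x$cumulative[x$n_components]),
      " of variance (threshold ",
      sprintf("%g%%", 100 * x$variance_fraction), ")\n", sep = "")
  invisible(x)
}

#' Project new data onto a PCA selection
#'
#' @param object A `pca_selection`.
#' @param newdata Numeric matrix with the same columns as the fitted data.
#' @param ... Unused.
#' @return Score matrix (n x k).
#' @export
predict.pca_selection <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2, object$center) %*% object$loadings
}
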