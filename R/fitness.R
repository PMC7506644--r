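#' Cross-validated SVM fitness of a feature subset
#'
#' The objective driving the wrapper genetic algorithm: the mean accuracy
#' (in percent) of a cubic-kernel one-vs-one SVM over stratified 10-fold
#' cross-validation, trained on the masked feature columns only. Folds are
#' derived deterministically from `cv_seed` and from the row *contents*
#' (rows are ordered lexicographically within each class before fold
#' labels are dealt), so the value does not depend on row order and is
#' identical for every mask evaluated within one GA run. Features are
#' standardized once on the full matrix before the CV loop; the kernel
#' Gram matrix of each candidate subset is then computed once and shared
#' across folds, which keeps a full GA run tractable. An empty mask has
#' fitness 0 by definition (it can never become the elite).
#'
#' @param mask Logical (or 0/1) vector over the feature columns.
#' @param x A `feature_matrix`, or a numeric matrix (then `y` is required).
#' @param y Class labels (ignored when `x` is a `feature_matrix`).
#' @param cv_seed Integer seed fixing the fold assignment.
#' @param folds Number of CV folds.
#' @param cost SVM box constraint.
#' @param degree Polynomial kernel degree (3 = cubic).
#' @return Accuracy in percent (scalar).
#' @export
fitness <- function(mask, x, y = NULL, cv_seed = 1L, folds = 10L,
                    cost = 1, degree = 3L) {
  d <- as_xy(x, y)
  if (is.null(d$y)) stop("class labels are required")
  mask <- as.logical(mask)
  if (length(mask) != ncol(d$X)) stop("mask length does not match features")
  if (!any(mask)) return(0)
  fold <- content_folds(d$X, d$y, folds, seed = cv_seed)
  Z <- standardize_columns(d$X[, mask, drop = FALSE])
  cpp_svm_ovo_cv(Z, as.integer(d$y), as.integer(fold),
                 n_class = nlevels(d$y), cost = cost,
                 degree = as.integer(degree), gamma = 1 / sum(mask))
}

# Center/scale columns; constant columns are centered only (scale 1), the
# same convention libsvm front ends use.
standardize_columns <- function(X, center = NULL, scale = NULL) {
  center <- center %||% colMeans(X)
  scale <- scale %||% apply(X, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  sweep(sweep(X, 2, center), 2, scale, "/")
}
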