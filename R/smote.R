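#' Balance classes by SMOTE oversampling
#'
#' Brings every class up to exactly `target_per_class` rows. Original rows
#' are kept; each synthetic row is `x + u * (x_nn - x)` where `x` is a
#' randomly drawn original row of the class, `x_nn` one of its
#' `k_neighbors` same-class (Euclidean) nearest neighbours and
#' `u ~ Uniform(0, 1)`, so every synthetic point lies on a segment between
#' two original same-class points.
#'
#' @param x A `feature_matrix` or numeric matrix.
#' @param y Labels (if `x` is a matrix).
#' @param target_per_class Desired per-class count; must be at least the
#'   largest current class count.
#' @param k_neighbors Neighbourhood size (default 5; capped at class
#'   size - 1).
#' @param seed Integer seed for the draws.
#' @return Same container as `x`: a `feature_matrix`, or a list
#'   `list(X, y)`. Synthetic rows are appended after the originals, with
#'   subject ids suffixed `_smote<i>`.
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' y <- rep(c("SU", "HA"), c(14, 6))
#' b <- smote_balance(X, y, target_per_class = 14, seed = 1)
#' table(b$y)
#' @export
smote_balance <- function(x, y = NULL, target_per_class, k_neighbors = 5L,
                          seed = NULL) {
  d <- as_xy(x, y)
  if (is.null(d$y)) stop("class labels are required")
  y0 <- droplevels(d$y)
  counts <- table(y0)
  if (target_per_class < max(counts)) {
    stop("target_per_class (", target_per_class,
         ") is below the largest class (", max(counts), ")")
  }
  if (any(counts[counts < target_per_class] < 2)) {
    stop("SMOTE needs at least 2 members in every class to oversample")
  }

  new_X <- list()
  new_y <- list()
  new_id <- list()
  with_seed(seed, {
    for (cl in levels(y0)) {
      idx <- which(y0 == cl)
      need <- target_per_class - length(idx)
      if (need <= 0) next
      Xc <- d$X[idx, , drop = FALSE]
      k <- min(k_neighbors, nrow(Xc) - 1L)
      D <- as.matrix(dist(Xc))
      diag(D) <- Inf
      nn <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
      base <- sample.int(nrow(Xc), need, replace = TRUE)
      pick <- vapply(base, function(b) nn[b, sample.int(k, 1)], integer(1))
      u <- runif(need)
      synth <- Xc[base, , drop = FALSE] +
        u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      new_X[[cl]] <- synth
      new_y[[cl]] <- rep(cl, need)
      new_id[[cl]] <- paste0(cl, "_smote", seq_len(need))
    }
  })

  X_out <- rbind(d$X, do.call(rbind, new_X))
  y_out <- factor(c(as.character(d$y), unlist(new_y)), levels = levels(d$y))
  subj <- c(d$subject %||% paste0("s", seq_len(nrow(d$X))), unlist(new_id))
  if (inherits(x, "feature_matrix")) {
    structure(list(X = X_out, y = y_out, subject = unname(subj),
                   catalog = x$catalog),
              class = "feature_matrix")
  } else {
    list(X = X_out, y = y_out)
  }
}
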