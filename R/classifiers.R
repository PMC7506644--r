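# The four classifiers of the study: cubic and quadratic polynomial-kernel
# one-vs-one SVMs, 1-nearest-neighbour, and a random-subspace kNN ensemble.

#' Classifier specification
#'
#' @param family `"svm_poly"` (one-vs-one SVM with polynomial kernel
#'   `(1 + x.y/d)^degree`, the stock library scaling `gamma = 1/d`),
#'   `"knn"` (k-nearest neighbour, default the
#'   "fine" k = 1), or `"subspace_knn"` (ensemble of `n_learners` kNN
#'   learners, each trained on a without-replacement random subset of
#'   `subspace_dims` features, combined by averaging the per-class
#'   scores).
#' @param degree Polynomial degree for `svm_poly` (2 or 3).
#' @param cost SVM box constraint.
#' @param k Neighbour count for `knn`.
#' @param n_learners Ensemble size (200, the stock default).
#' @param subspace_dims Features per weak learner; `NULL` means
#'   `round(d / 2)` where `d` is the training feature count.
#' @param standardize Standardize features using training-split statistics.
#' @param seed Seed for the ensemble's random subspaces.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm_poly", "knn", "subspace_knn"),
                            degree = 3L, cost = 1, k = 1L,
                            n_learners = 200L, subspace_dims = NULL,
                            standardize = TRUE, seed = NULL) {
  family <- match.arg(family)
  if (family == "svm_poly") stopifnot(degree %in% c(2L, 3L))
  stopifnot(k >= 1, n_learners >= 1)
  structure(list(family = family, degree = as.integer(degree), cost = cost,
                 k = as.integer(k), n_learners = as.integer(n_learners),
                 subspace_dims = subspace_dims, standardize = standardize,
                 seed = seed),
            class = "classifier_spec")
}

#' Shorthand specs matching the study's classifier names
#'
#' `svm3()`/`svm2()`: cubic/quadratic-kernel one-vs-one SVM; `knn1()`:
#' "fine" 1-nearest-neighbour; `eknn()`: random-subspace kNN ensemble
#' (200 learners on `round(d/2)`-feature subspaces).
#'
#' @param ... Passed on to [classifier_spec()].
#' @return A `classifier_spec`.
#' @export
svm3 <- function(...) classifier_spec("svm_poly", degree = 3L, ...)

#' @rdname svm3
#' @export
svm2 <- function(...) classifier_spec("svm_poly", degree = 2L, ...)

#' @rdname svm3
#' @export
knn1 <- function(...) classifier_spec("knn", k = 1L, ...)

#' @rdname svm3
#' @export
eknn <- function(...) classifier_spec("subspace_knn", ...)

#' Train a classifier and predict test labels
#'
#' @param spec A [classifier_spec()] (or a stub: a function
#'   `f(X_train, y_train, X_test)` returning labels, used for protocol
#'   tests).
#' @param X_train,X_test Numeric matrices with matching columns.
#' @param y_train Training labels.
#' @return Factor of predicted labels (levels of `y_train`), with a
#'   `"scores"` attribute (n x class matrix: vote counts for the SVM,
#'   averaged neighbour scores for the ensembles).
#' @export
train_predict <- function(spec, X_train, y_train, X_test) {
  if (is.function(spec)) return(spec(X_train, y_train, X_test))
  stopifnot(inherits(spec, "classifier_spec"))
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  if (ncol(X_test) != ncol(X_train)) {
    stop("test data has ", ncol(X_test), " features, training data ",
         ncol(X_train))
  }
  y_train <- droplevels(as.factor(y_train))
  if (nlevels(y_train) < 2) stop("training data needs at least two classes")
  if (spec$standardize) {
    ctr <- colMeans(X_train)
    scl <- apply(X_train, 2, sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    X_train <- standardize_columns(X_train, ctr, scl)
    X_test <- standardize_columns(X_test, ctr, scl)
  }
  switch(spec$family,
         svm_poly = predict_svm_ovo(spec, X_train, y_train, X_test),
         knn = predict_knn(spec$k, X_train, y_train, X_test),
         subspace_knn = predict_subspace_knn(spec, X_train, y_train, X_test))
}

# One-vs-one polynomial SVM via libsvm (e1071), which itself builds the
# C(C-1)/2 binary machines and combines them by majority vote. Vote counts
# are recovered from the pairwise decision values so ties can be broken by
# the package-wide rule (lowest class index in the fixed order).
predict_svm_ovo <- function(spec, X_train, y_train, X_test) {
  fit <- e1071::svm(X_train, y_train, kernel = "polynomial",
                    degree = spec$degree, gamma = 1 / ncol(X_train), coef0 = 1,
                    cost = spec$cost, scale = FALSE)
  dec <- attr(predict(fit, X_test, decision.values = TRUE),
              "decision.values")
  lv <- levels(y_train)
  votes <- matrix(0L, nrow(X_test), length(lv), dimnames = list(NULL, lv))
  for (cn in colnames(dec)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    win <- ifelse(dec[, cn] >= 0, pair[1], pair[2])
    for (cl in pair) votes[, cl] <- votes[, cl] + (win == cl)
  }
  ovo_decide(votes, lv)
}

# argmax with ties to the lowest class index in level order
ovo_decide <- function(votes, lv) {
  pred <- factor(lv[apply(votes, 1, which.max)], levels = lv)
  attr(pred, "scores") <- votes
  pred
}

predict_knn <- function(k, X_train, y_train, X_test) {
  lv <- levels(y_train)
  D2 <- outer(rowSums(X_test^2), rowSums(X_train^2), "+") -
    2 * tcrossprod(X_test, X_train)
  scores <- matrix(0, nrow(X_test), length(lv), dimnames = list(NULL, lv))
  for (i in seq_len(nrow(X_test))) {
    nn <- order(D2[i, ])[seq_len(k)]
    tab <- table(factor(y_train[nn], levels = lv)) / k
    scores[i, ] <- as.numeric(tab)
  }
  ovo_decide(scores, lv)
}

# Random-subspace ensemble: n_learners kNN learners, each on a
# without-replacement draw of subspace_dims features; the class with the
# highest average score (neighbour fraction) wins.
predict_subspace_knn <- function(spec, X_train, y_train, X_test) {
  d <- ncol(X_train)
  m <- spec$subspace_dims %||% max(1L, round(d / 2))
  if (m > d) stop("subspace_dims exceeds the feature count")
  lv <- levels(y_train)
  scores <- matrix(0, nrow(X_test), length(lv), dimnames = list(NULL, lv))
  with_seed(spec$seed, {
    for (b in seq_len(spec$n_learners)) {
      cols <- sample.int(d, m)
      p <- predict_knn(spec$k, X_train[, cols, drop = FALSE], y_train,
                       X_test[, cols, drop = FALSE])
      scores <- scores + attr(p, "scores")
    }
  })
  ovo_decide(scores / spec$n_learners, lv)
}
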