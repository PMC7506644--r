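# Stratified fold assignment.
#
# Two flavours are used in the package:
#  * shuffle folds  -- ordinary seeded stratified folds, one fresh draw per
#    repetition of the evaluation protocol;
#  * content folds  -- fold labels assigned to rows *sorted by content*
#    within each class, so the assignment depends only on (values, label,
#    seed) and not on row order. The GA fitness uses these, which makes
#    fitness invariant to permuting the rows of the training matrix.
# Both deal fold labels per class as a shuffled rep(1:k), so per-fold class
# counts never deviate from perfect stratification by more than one row.

stratified_folds <- function(y, k, seed = NULL) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    stop("every class needs at least ", k,
         " rows for ", k, "-fold stratification; balance first (see smote_balance)")
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

content_folds <- function(X, y, k, seed = NULL) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    stop("every class needs at least ", k, " rows for stratified folds")
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (ci in seq_along(levels(y))) {
      idx <- which(y == levels(y)[ci])
      # lexicographic order of the row contents: permutation-invariant
      ord <- do.call(order, c(lapply(seq_len(ncol(X)),
                                     function(j) X[idx, j]),
                              list(method = "radix")))
      labels <- sample(rep_len(seq_len(k), length(idx)))
      fold[idx[ord]] <- labels
    }
  })
  fold
}
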