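#' Repeated stratified cross-validation of a classifier
#'
#' Runs `n_repetitions` independent stratified `folds`-fold
#' cross-validations (a fresh stratified shuffle per repetition). The
#' accuracy of one repetition is the mean of its per-fold accuracies; the
#' report summarizes the repetition accuracies (standard deviation,
#' median, mean, maximum, minimum) and pools all test predictions into a
#' row-normalized confusion matrix in the fixed class order
#' `SU SA HA FE DI AN`.
#'
#' @param spec A [classifier_spec()] or a stub function
#'   `f(X_train, y_train, X_test)`.
#' @param x A `feature_matrix` or numeric matrix.
#' @param y Labels (if `x` is a matrix).
#' @param n_repetitions Number of repeated CVs (default 10).
#' @param folds Folds per repetition (default 10).
#' @param seed Master seed; repetition `r` uses `seed + r - 1` for its
#'   fold shuffle.
#' @param fold_summary Summarize over individual folds instead of
#'   repetition means (alternative reading of the protocol).
#' @return A `cv_report`: list with `repetition_accuracy` (percent),
#'   `summary` (named vector: sd, median, mean, max, min), `confusion`
#'   (row-normalized percent, rows = true class), `confusion_counts`,
#'   `n_repetitions`, `folds`, `seed`.
#' @examples
#' faces <- generate_dataset(synthetic_config(n_per_class = 12, seed = 1))
#' fm <- extract_feature_matrix(faces)
#' evaluate(knn1(), fm, n_repetitions = 2, seed = 1)
#' @export
evaluate <- function(spec, x, y = NULL, n_repetitions = 10L, folds = 10L,
                     seed = 1L, fold_summary = FALSE) {
  d <- as_xy(x, y)
  if (is.null(d$y)) stop("class labels are required")
  yf <- droplevels(d$y)
  if (any(table(yf) < folds)) {
    stop("some class has fewer than ", folds,
         " rows; balance first (see smote_balance)")
  }
  lv <- levels(yf)
  conf <- matrix(0, length(lv), length(lv), dimnames = list(true = lv,
                                                            predicted = lv))
  rep_acc <- numeric(n_repetitions)
  fold_acc <- numeric(0)
  for (r in seq_len(n_repetitions)) {
    fold <- stratified_folds(yf, folds, seed = seed + r - 1L)
    accs <- numeric(folds)
    for (f in seq_len(folds)) {
      te <- fold == f
      pred <- train_predict(spec, d$X[!te, , drop = FALSE], yf[!te],
                            d$X[te, , drop = FALSE])
      pred <- factor(as.character(pred), levels = lv)
      accs[f] <- mean(pred == yf[te])
      conf <- conf + table(factor(yf[te], levels = lv), pred)
    }
    rep_acc[r] <- 100 * mean(accs)
    fold_acc <- c(fold_acc, 100 * accs)
  }
  basis <- if (fold_summary) fold_acc else rep_acc
  structure(list(repetition_accuracy = rep_acc,
                 fold_accuracy = fold_acc,
                 summary = c(sd = sd(basis), median = median(basis),
                             mean = mean(basis), max = max(basis),
                             min = min(basis)),
                 confusion = 100 * conf / pmax(rowSums(conf), 1),
                 confusion_counts = conf,
                 n_repetitions = n_repetitions, folds = folds, seed = seed,
                 fold_summary = fold_summary),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 2, ...) {
  cat("<cv_report> ", x$n_repetitions, " x ", x$folds, "-fold stratified CV\n",
      sep = "")
  s <- x$summary
  cat(sprintf("  Standard deviation %6.2f\n  Median accuracy    %6.2f\n",
              s["sd"], s["median"]))
  cat(sprintf("  Mean accuracy      %6.2f\n  Maximum accuracy   %6.2f\n",
              s["mean"], s["max"]))
  cat(sprintf("  Minimum accuracy   %6.2f\n", s["min"]))
  cat("  Confusion matrix (% of true class):\n")
  print(round(x$confusion))
  invisible(x)
}

#' Serialize a CV report to JSON / confusion matrix to CSV
#'
#' @param report A `cv_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  jsonlite::write_json(
    list(n_repetitions = report$n_repetitions, folds = report$folds,
         seed = report$seed,
         repetition_accuracy = report$repetition_accuracy,
         summary = as.list(report$summary),
         confusion_percent = as.data.frame(unclass(report$confusion)),
         class_order = rownames(report$confusion)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
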