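# SMOTE balancing, the four classifiers, and the evaluation protocol.

test_that("smote balances the published class counts to the target", {
  set.seed(21)
  counts <- c(SU = 63, SA = 66, HA = 99, FE = 62, DI = 64, AN = 70)
  X <- matrix(rnorm(sum(counts) * 5), ncol = 5)
  y <- factor(rep(names(counts), counts), levels = names(counts))
  out <- smote_balance(X, y, target_per_class = 104, seed = 1)
  expect_true(all(table(out$y) == 104))
  expect_equal(nrow(out$X), 624)
  # originals retained, in place
  expect_identical(out$X[seq_len(nrow(X)), ], X)
})

test_that("smote is a no-op on already balanced data and validates inputs", {
  d <- toy_six_class(n_per_class = 8, seed = 22)
  out <- smote_balance(d$X, d$y, target_per_class = 8, seed = 1)
  expect_identical(out$X, d$X)
  expect_error(smote_balance(d$X, d$y, target_per_class = 5), "largest class")
  X1 <- rbind(d$X, 0)
  y1 <- factor(c(as.character(d$y), "XX"), levels = c(levels(d$y), "XX"))
  expect_error(smote_balance(X1, y1, target_per_class = 8), "at least 2")
})

test_that("every synthetic smote point lies on a same-class segment", {
  set.seed(23)
  X <- matrix(runif(30 * 2), 30, 2)
  y <- factor(rep(c("SU", "HA"), c(20, 10)), levels = c("SU", "HA"))
  out <- smote_balance(X, y, target_per_class = 20, seed = 9)
  synth <- out$X[-seq_len(30), , drop = FALSE]
  expect_equal(nrow(synth), 10)
  orig_ha <- X[y == "HA", ]
  on_segment <- function(p) {
    for (i in 1:(nrow(orig_ha) - 1)) {
      for (j in (i + 1):nrow(orig_ha)) {
        a <- orig_ha[i, ]; b <- orig_ha[j, ]
        v <- b - a; w <- p - a
        cross <- v[1] * w[2] - v[2] * w[1]
        t <- sum(w * v) / sum(v * v)
        if (abs(cross) < 1e-8 && t >= -1e-9 && t <= 1 + 1e-9) return(TRUE)
      }
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_segment)))
})

test_that("one-vs-one vote tallies pick the argmax with ties to the lowest class", {
  lv <- expression_levels()
  votes <- rbind(c(5, 0, 0, 0, 0, 0),
                 c(1, 1, 4, 3, 1, 0),
                 c(3, 3, 0, 1, 1, 2),   # tie SU/SA -> SU
                 c(0, 2, 2, 2, 1, 1))   # tie SA/HA/FE -> SA
  colnames(votes) <- lv
  pred <- geomexpr:::ovo_decide(votes, lv)
  expect_equal(as.character(pred), c("SU", "HA", "SU", "SA"))
})

test_that("1-NN perfectly predicts its own training points", {
  d <- toy_six_class(n_per_class = 6, sep = 1, seed = 24)
  pred <- train_predict(knn1(), d$X, d$y, d$X)
  expect_equal(as.character(pred), as.character(d$y))
})

test_that("polynomial svm decision values on the XOR toy match the closed-form QP solution", {
  # 4-point XOR at (+-1, +-1); by symmetry all dual variables are equal:
  # maximizing 4a - a^2/2 * sum_ij y_i y_j K_ij gives a* = min(C, 4/S)
  X <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  yv <- c(1, 1, -1, -1)
  gam <- 1 / 2
  K <- (1 + gam * tcrossprod(X))^3
  S <- sum(outer(yv, yv) * K)
  C <- 1
  a_star <- min(C, 4 / S)
  f_oracle <- as.numeric(K %*% (a_star * yv))  # b = 0 by symmetry

  sol <- geomexpr:::cpp_smo_binary(K, as.integer(yv), C, eps = 1e-9)
  expect_equal(sol$alpha, rep(a_star, 4), tolerance = 1e-6)
  expect_equal(sol$b, 0, tolerance = 1e-6)
  f_smo <- as.numeric(K %*% (sol$alpha * yv)) + sol$b
  expect_equal(f_smo, f_oracle, tolerance = 1e-6)

  # the e1071-backed classifier separates the same toy with the same kernel
  y <- factor(c("SU", "SU", "SA", "SA"), levels = c("SU", "SA"))
  fit <- e1071::svm(X, y, kernel = "polynomial", degree = 3, gamma = gam,
                    coef0 = 1, cost = C, scale = FALSE)
  dec <- as.numeric(attr(predict(fit, X, decision.values = TRUE),
                         "decision.values"))
  expect_equal(dec, f_oracle, tolerance = 1e-3)
})

test_that("svm2 and svm3 differ exactly by the kernel exponent", {
  set.seed(25)
  X <- rbind(matrix(rnorm(20 * 3, -1.5), ncol = 3),
             matrix(rnorm(20 * 3, 1.5), ncol = 3))
  y <- factor(rep(c("SU", "SA"), each = 20), levels = c("SU", "SA"))
  for (deg in 2:3) {
    fit <- e1071::svm(X, y, kernel = "polynomial", degree = deg,
                      gamma = 1 / 3, coef0 = 1, cost = 1, scale = FALSE)
    # reconstruct the decision function from the support vectors and the
    # direct kernel evaluation (1 + x.y/3)^deg: only the exponent differs
    Ktest <- (1 + tcrossprod(X, fit$SV) / 3)^deg
    manual <- as.numeric(Ktest %*% fit$coefs - fit$rho)
    dec <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
    expect_equal(manual, as.numeric(dec), tolerance = 1e-8)
  }
})

test_that("subspace ensemble with full subspaces reduces to plain kNN", {
  d <- toy_six_class(n_per_class = 6, sep = 2, seed = 26)
  q <- toy_six_class(n_per_class = 3, sep = 2, seed = 27)
  full <- eknn(n_learners = 5, subspace_dims = ncol(d$X), seed = 1)
  p1 <- train_predict(full, d$X, d$y, q$X)
  p2 <- train_predict(knn1(), d$X, d$y, q$X)
  expect_equal(as.character(p1), as.character(p2))
  sc <- attr(p1, "scores")
  expect_equal(unname(rowSums(sc)), rep(1, nrow(q$X)))
})

test_that("subspace ensemble averages per-learner scores over random subspaces", {
  # two informative columns that disagree: learner predictions depend on
  # which column a subspace draws, and scores average across learners
  X <- cbind(c(-1, -1, 1, 1), c(1, 1, -1, -1)) * 5
  y <- factor(c("SU", "SU", "SA", "SA"), levels = c("SU", "SA"))
  Xte <- rbind(c(5, 5))  # column 1 says SA, column 2 says SU
  p <- train_predict(eknn(n_learners = 200, subspace_dims = 1, seed = 42,
                          standardize = FALSE), X, y, Xte)
  sc <- attr(p, "scores")
  expect_equal(unname(rowSums(sc)), 1)
  # both classes get a substantial share of the averaged score
  expect_gt(min(sc), 0.3)
})

test_that("the evaluation protocol is exact for an oracle stub", {
  d <- toy_six_class(n_per_class = 12, seed = 28)
  rep <- evaluate(make_oracle_stub(d$X, d$y), d$X, d$y,
                  n_repetitions = 3, seed = 1)
  expect_true(all(rep$repetition_accuracy == 100))
  expect_equal(unname(rep$summary[c("mean", "median", "max", "min")]),
               rep(100, 4))
  expect_equal(unname(rep$summary["sd"]), 0)
  expect_equal(unname(diag(rep$confusion)), rep(100, 6))
  expect_equal(sum(rep$confusion), 600)
})

test_that("a uniform random guess scores near chance on balanced six-class data", {
  d <- toy_six_class(n_per_class = 12, seed = 29)
  set.seed(30)
  rep <- evaluate(random_stub, d$X, d$y, n_repetitions = 50, seed = 1)
  expect_lt(abs(rep$summary[["mean"]] - 100 / 6), 3)
})

test_that("stratified folds deviate from perfect balance by at most one per class", {
  y <- factor(rep(expression_levels(), times = c(17, 23, 11, 30, 14, 26)))
  fold <- geomexpr:::stratified_folds(y, 10, seed = 31)
  for (cl in levels(y)) {
    per_fold <- tabulate(fold[y == cl], nbins = 10)
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("cv reports are reproducible under a fixed seed", {
  d <- toy_six_class(n_per_class = 10, seed = 32)
  r1 <- evaluate(knn1(), d$X, d$y, n_repetitions = 2, seed = 7)
  r2 <- evaluate(knn1(), d$X, d$y, n_repetitions = 2, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(abs(rowSums(r1$confusion) - 100) < 1e-9))
  s <- r1$summary
  expect_lte(s[["min"]], s[["median"]])
  expect_lte(s[["median"]], s[["max"]])
  expect_gte(s[["sd"]], 0)
})

test_that("evaluation refuses classes smaller than the fold count", {
  d <- toy_six_class(n_per_class = 4, seed = 33)
  expect_error(evaluate(knn1(), d$X, d$y, n_repetitions = 1), "smote_balance")
})

test_that("mismatched train/test feature counts are rejected", {
  d <- toy_six_class(n_per_class = 6, seed = 34)
  expect_error(train_predict(knn1(), d$X, d$y, d$X[, 1:3]), "features")
})
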