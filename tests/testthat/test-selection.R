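# PCA variance thresholding and the wrapper GA.

# scores with exactly orthogonal, zero-mean columns and prescribed variances
spectrum_data <- function(n, lambdas) {
  S <- sapply(seq_along(lambdas), function(j) sin(2 * pi * j * (1:n) / n))
  S <- scale(S, center = TRUE, scale = FALSE)
  S <- qr.Q(qr(S)) * sqrt(n - 1)
  sweep(S, 2, sqrt(lambdas), "*")
}

test_that("pca_select keeps the minimal component count for a known spectrum", {
  X <- spectrum_data(40, c(9, 0.5, 0.5))  # cumulative fractions .9, .95, 1
  expect_equal(pca_select(X, 0.90)$n_components, 1)
  expect_equal(pca_select(X, 0.95)$n_components, 2)
  expect_equal(pca_select(X, 0.9999)$n_components, 3)
})

test_that("degenerate and full-retention cases behave", {
  set.seed(11)
  v <- rnorm(5)
  scores <- rnorm(30)
  rank1 <- outer(scores, v) + matrix(rep(rnorm(5), each = 30), 30)
  expect_equal(pca_select(rank1, 0.9999)$n_components, 1)
  full <- matrix(rnorm(20 * 89), 20, 89)
  expect_equal(pca_select(full, 1)$n_components, min(20 - 1, 89))
  expect_error(pca_select(full, 0), "variance_fraction")
  expect_error(pca_select(full, -1), "variance_fraction")
})

test_that("pca_select agrees with an explicit covariance eigendecomposition", {
  set.seed(12)
  X <- matrix(rnorm(25 * 7), 25, 7) %*% diag(c(5, 3, 2, 1, 1, .5, .1))
  sel <- pca_select(X, 0.99)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(sel$cumulative, cumsum(ev / sum(ev)), tolerance = 1e-8)
  # scores really are the centered projections
  expect_equal(sel$scores,
               sweep(X, 2, colMeans(X)) %*% sel$loadings,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_gte(sel$cumulative[sel$n_components], 0.99)
  if (sel$n_components > 1) {
    expect_lt(sel$cumulative[sel$n_components - 1], 0.99)
  }
})

test_that("fitness is 100 on linearly separable data and 0 on the empty mask", {
  set.seed(13)
  X <- cbind(c(rnorm(20, -8), rnorm(20, 8)), matrix(rnorm(40 * 4), 40))
  y <- rep(c("SU", "HA"), each = 20)
  expect_equal(fitness(rep(TRUE, 5), X, y, cv_seed = 1), 100)
  expect_equal(fitness(rep(FALSE, 5), X, y, cv_seed = 1), 0)
})

test_that("fitness is deterministic and invariant to row permutation", {
  d <- toy_six_class(n_per_class = 12, sep = 3, seed = 14)
  mask <- rep(c(TRUE, FALSE), each = 4)
  f1 <- fitness(mask, d$X, d$y, cv_seed = 5)
  f2 <- fitness(mask, d$X, d$y, cv_seed = 5)
  expect_identical(f1, f2)
  set.seed(15)
  perm <- sample(nrow(d$X))
  expect_identical(fitness(mask, d$X[perm, ], d$y[perm], cv_seed = 5), f1)
  # different folds give a (generally) different estimate
  expect_false(identical(f1, fitness(mask, d$X, d$y, cv_seed = 6)) &&
                 identical(f1, fitness(mask, d$X, d$y, cv_seed = 7)))
})

test_that("planted features outscore their complement almost surely", {
  # small-scale simulation oracle: only the planted columns carry signal
  set.seed(16)
  wins <- 0
  for (rep in 1:60) {
    d <- toy_six_class(n_per_class = 10, p = 12, sep = 0, seed = 1000 + rep)
    H <- matrix(sample(c(-1, 1), 6 * 4, replace = TRUE), 6)
    planted <- c(1, 4, 7, 10)
    d$X[, planted] <- d$X[, planted] + 2.5 * H[as.integer(d$y), ]
    pm <- seq_len(12) %in% planted
    if (fitness(pm, d$X, d$y, cv_seed = rep) >
        fitness(!pm, d$X, d$y, cv_seed = rep)) wins <- wins + 1
  }
  expect_gte(wins / 60, 0.95)
})

test_that("one-point crossover splices exactly at the cut", {
  a <- rep(TRUE, 9)
  b <- rep(FALSE, 9)
  for (k in c(1, 4, 8)) {
    ch <- one_point_crossover(a, b, k)
    expect_equal(ch[[1]], c(rep(TRUE, k), rep(FALSE, 9 - k)))
    expect_equal(ch[[2]], c(rep(FALSE, k), rep(TRUE, 9 - k)))
  }
  expect_error(one_point_crossover(a, b, 9))
})

test_that("ga_select honours elitism and the determinism contract", {
  d <- toy_six_class(n_per_class = 12, p = 10, sep = 2.5, seed = 17)
  cfg <- ga_config(generations = 8, rng_seed = 3, cv_seed = 4)
  res1 <- ga_select(d$X, d$y, cfg)
  res2 <- ga_select(d$X, d$y, cfg)
  expect_identical(res1, res2)                       # bit-identical rerun
  expect_true(all(diff(res1$fitness_history) >= 0))  # elitism monotonicity
  expect_equal(res1$best_fitness,
               res1$fitness_history[length(res1$fitness_history)])
  expect_gte(sum(res1$best_mask), 1)
  # a different seed explores a different trajectory
  cfg2 <- cfg
  cfg2$rng_seed <- 99L
  expect_false(identical(ga_select(d$X, d$y, cfg2)$mean_history,
                         res1$mean_history))
})

test_that("ga configuration is validated", {
  expect_error(ga_config(population_size = 7), "population_size")
  expect_error(ga_config(mutation_rate = 1.5), "mutation_rate")
  d <- toy_six_class(n_per_class = 5, seed = 18)  # < 10 per class
  expect_error(ga_select(d$X, d$y, ga_config(generations = 1)), "10")
})
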