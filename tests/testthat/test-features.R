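test_that("catalog has 89 descriptors with the expected group structure", {
  cat89 <- feature_catalog()
  expect_equal(nrow(cat89), 89)
  expect_equal(unname(catalog_group_counts(cat89)), c(27, 19, 20, 23))
  expect_false(anyDuplicated(cat89$id) > 0)
  # block order: 3D distances, 3D angles, 2D distances, 2D angles
  expect_equal(cat89$id[1], "1D3")
  expect_equal(cat89$id[20], "1A3")
  expect_equal(cat89$id[47], "1D2")
  expect_equal(cat89$id[70], "1A2")
})

test_that("published selected subset is a 47-feature sub-catalog", {
  mask <- ga_selected_mask()
  expect_equal(sum(mask), 47)
  expect_equal(unname(catalog_group_counts(ga_selected_catalog())),
               c(14, 12, 8, 13))
  expect_true(all(ids_from_mask(mask) %in% feature_catalog()$id))
})

test_that("euclidean distance matches a coordinate-wise oracle", {
  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(101)
  for (i in 1:1000) {
    p <- rnorm(3, sd = 50)
    q <- rnorm(3, sd = 50)
    oracle <- sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2 + (p[3] - q[3])^2)
    expect_equal(euclidean_distance(p, q), oracle, tolerance = 1e-12)
  }
})

test_that("vertex angle matches a law-of-cosines oracle", {
  expect_equal(landmark_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), pi / 2)
  expect_equal(landmark_angle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), pi)
  set.seed(202)
  worst <- 0
  for (i in 1:1000) {
    p1 <- rnorm(3, sd = 20); p2 <- rnorm(3, sd = 20); p3 <- rnorm(3, sd = 20)
    a <- euclidean_distance(p1, p2)
    b <- euclidean_distance(p3, p2)
    cc <- euclidean_distance(p1, p3)
    oracle <- acos(max(-1, min(1, (a^2 + b^2 - cc^2) / (2 * a * b))))
    worst <- max(worst, abs(landmark_angle(p1, p2, p3) - oracle))
  }
  expect_lt(worst, 1e-9)
})

test_that("angle arguments are clamped so collinear fuzz never yields NaN", {
  set.seed(303)
  for (i in 1:200) {
    d <- rnorm(3)
    d <- d / sqrt(sum(d^2))
    o <- rnorm(3, sd = 10)
    s <- runif(2, 0.1, 3)
    # exactly collinear up to floating point, both orientations
    expect_false(is.nan(landmark_angle(o + s[1] * d, o, o + s[2] * d)))
    expect_false(is.nan(landmark_angle(o + s[1] * d, o, o - s[2] * d)))
  }
})

test_that("degenerate angle arms raise identifying errors", {
  p <- c(1, 1, 1)
  expect_error(landmark_angle(p, p, c(0, 0, 0)), "first arm")
  expect_error(landmark_angle(c(0, 0, 0), p, p), "third arm")
  # propagated with the descriptor id attached
  pts <- neutral_template()$points
  pts[17, ] <- pts[16, ]  # collapses vertex 16 onto arm point 17 (8A3 etc.)
  expect_error(extract_features(landmark_set(pts)), "A")
})

test_that("normalizer is the landmark 8-9 distance and cancels scale", {
  tpl <- neutral_template()
  expect_equal(normalizer(tpl), 33)
  f <- extract_features(tpl)
  scaled <- transform_landmarks(tpl, scale = 3)
  moved <- transform_landmarks(tpl, translation = c(5, -12, 40))
  expect_equal(extract_features(scaled), f, tolerance = 1e-12)
  expect_equal(extract_features(moved), f, tolerance = 1e-9)
})

test_that("a constructed fixture gives unit normalized distance", {
  pts <- neutral_template()$points
  pts[1, ] <- c(0, 0, 0)   # descriptor 1D3 = d(p1, p3) / d(p8, p9)
  pts[3, ] <- c(0, 2, 0)
  pts[8, ] <- c(-1, 50, 0)
  pts[9, ] <- c(1, 50, 0)  # d(8, 9) = 2
  f <- extract_features(landmark_set(pts))
  expect_equal(unname(f["1D3"]), 1)
})

test_that("3D features are invariant under global similarity transforms", {
  set.seed(404)
  cat3d <- feature_catalog()
  is3d <- cat3d$space == "3D"
  for (i in 1:10) {
    ls <- toy_landmarks(shift = rnorm(1, sd = 4))
    f0 <- extract_features(ls)
    moved <- transform_landmarks(ls, random_rotation(),
                                 rnorm(3, sd = 100), runif(1, 0.2, 5))
    f1 <- extract_features(moved)
    expect_lt(max(abs(f1[is3d] - f0[is3d])), 1e-9)
  }
})

test_that("2D features are invariant in-plane but not out-of-plane", {
  set.seed(505)
  cat89 <- feature_catalog()
  is2d <- cat89$space == "2D"
  ls <- neutral_template()
  f0 <- extract_features(ls)
  for (i in 1:5) {
    inplane <- transform_landmarks(ls, rotation_matrix(rz = runif(1, 0, 2 * pi)),
                                   c(rnorm(2, sd = 30), 0), runif(1, 0.5, 2))
    f1 <- extract_features(inplane)
    expect_lt(max(abs(f1[is2d] - f0[is2d])), 1e-9)
  }
  tilted <- transform_landmarks(ls, rotation_matrix(rx = 0.6))
  f2 <- extract_features(tilted)
  expect_gt(max(abs(f2[is2d] - f0[is2d])), 1e-3)
})

test_that("feature matrices keep catalog column order; shuffling rows only permutes rows", {
  set.seed(606)
  faces <- generate_dataset(synthetic_config(n_per_class = 2, seed = 3))
  fm <- extract_feature_matrix(faces)
  expect_identical(colnames(fm$X), feature_catalog()$id)
  perm <- sample(length(faces))
  fm2 <- extract_feature_matrix(faces[perm])
  expect_identical(fm2$X, fm$X[perm, ])
  expect_identical(as.character(fm2$y), as.character(fm$y)[perm])
})

test_that("feature CSV round trip preserves values and labels", {
  fm <- extract_feature_matrix(generate_dataset(synthetic_config(n_per_class = 2, seed = 4)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fm, path)
  back <- read_features_csv(path)
  expect_identical(back$X, fm$X)
  expect_identical(as.character(back$y), as.character(fm$y))
})
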