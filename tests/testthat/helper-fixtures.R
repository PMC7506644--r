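# Fixtures built in code: no binary data, everything deterministic.

# A landmark set with arbitrary but valid geometry, offset per subject.
toy_landmarks <- function(subject = "t1", expression = "SU", shift = 0) {
  pts <- neutral_template()$points + shift
  landmark_set(pts, subject_id = subject, expression = expression)
}

# Random rotation matrix (uniform axis, uniform angle).
random_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  Kx <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
}

# Write a Bosphorus-style landmark file for the template (plus ear points).
write_bosphorus_fixture <- function(path, drop = NULL, mangle_line = NULL) {
  nms <- canonical_landmark_names()
  pts <- neutral_template()$points
  recs <- lapply(1:22, function(i) {
    list(name = nms[[i]], xyz = pts[i, ])
  })
  recs <- c(recs, list(list(name = "Left ear lobe", xyz = c(-80, 5, -40)),
                       list(name = "Right ear lobe", xyz = c(80, 5, -40))))
  if (!is.null(drop)) recs <- recs[-drop]
  lines <- c("landmark fixture", length(recs))
  for (r in recs) {
    lines <- c(lines, r$name, paste(format(r$xyz, digits = 17), collapse = " "))
  }
  if (!is.null(mangle_line)) lines[mangle_line] <- "1.0 not-a-number"
  writeLines(lines, path)
  path
}

# A raw 51-point set laid over a rough face, with the donor points used by
# the default adaptation map at controlled positions.
toy_uibvfed <- function(subject = "u1", expression = "HA") {
  nms <- c(paste0("eyebrow_left_", 1:5), paste0("eyebrow_right_", 1:5),
           paste0("nose_bridge_", 1:4), paste0("nose_lower_", 1:5),
           paste0("eye_left_", 1:6), paste0("eye_right_", 1:6),
           paste0("mouth_outer_", 1:12), paste0("mouth_inner_", 1:8))
  pts <- matrix(rnorm(51 * 3, sd = 5), 51, 3, dimnames = list(nms, NULL))
  # pin the landmarks that map to canonical points to template-like spots
  tpl <- neutral_template()$points
  pin <- c(eyebrow_left_1 = 1, eyebrow_left_3 = 2, eyebrow_left_5 = 3,
           eyebrow_right_1 = 4, eyebrow_right_3 = 5, eyebrow_right_5 = 6,
           eye_left_1 = 7, eye_left_4 = 8, eye_right_1 = 9, eye_right_4 = 10,
           nose_lower_1 = 13, nose_bridge_4 = 14, nose_lower_5 = 15,
           mouth_outer_1 = 16, mouth_outer_4 = 17, mouth_outer_7 = 18,
           mouth_inner_3 = 19, mouth_inner_7 = 20, mouth_outer_10 = 21)
  for (nm in names(pin)) pts[nm, ] <- tpl[pin[[nm]], ]
  pts["nose_bridge_1", ] <- c(0, 36, 9)
  pts["mouth_outer_9", ] <- c(-8, -34, 9)
  pts["mouth_outer_11", ] <- c(8, -34, 9)
  uibvfed_set(pts, subject_id = subject, expression = expression)
}

# Small separable six-class feature dataset for classifier tests: class
# means on a simplex in the first columns, standard normal noise.
toy_six_class <- function(n_per_class = 12, p = 8, sep = 6, seed = 1) {
  set.seed(seed)
  lv <- expression_levels()
  X <- matrix(rnorm(6 * n_per_class * p), ncol = p)
  y <- factor(rep(lv, each = n_per_class), levels = lv)
  for (c in 1:6) {
    mu <- rep(0, p)
    mu[c %% p + 1] <- sep
    mu[(2 * c) %% p + 1] <- -sep / 2
    X[as.integer(y) == c, ] <- X[as.integer(y) == c, ] +
      matrix(mu, n_per_class, p, byrow = TRUE)
  }
  list(X = X, y = y)
}

# Stub classifiers for the evaluation-protocol tests: the oracle stub
# looks the true label up by row content, the random stub guesses.
make_oracle_stub <- function(X_all, y_all) {
  key <- apply(round(X_all, 10), 1, paste, collapse = ",")
  lookup <- setNames(as.character(y_all), key)
  function(X_train, y_train, X_test) {
    k <- apply(round(X_test, 10), 1, paste, collapse = ",")
    factor(lookup[k], levels = levels(y_train))
  }
}

random_stub <- function(X_train, y_train, X_test) {
  factor(sample(levels(y_train), nrow(X_test), replace = TRUE),
         levels = levels(y_train))
}
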