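# Synthetic labeled 22-landmark faces. The generator exists so the whole
# pipeline (extraction -> selection -> classification) is exercisable and
# testable without any external face database: a fixed anthropometric
# neutral template is deformed by qualitative per-expression displacement
# fields (brows raised for surprise, inner brows pulled down and together
# for anger, asymmetric upper-lip raise for disgust, ...), modulated by a
# random activation strength, identity jitter, measurement noise, and a
# random global similarity transform for pose/size variation.

#' The neutral face template
#'
#' A fixed, bilaterally symmetric 22-landmark frontal face at millimetre
#' scale (inner eye corners 33 mm apart), shipped as an editable data
#' file. All synthetic faces are deformations of this template.
#'
#' @return A [landmark_set()] with `subject_id = "template"`.
#' @export
neutral_template <- function() {
  df <- read.csv(extdata_path("neutral_template.csv"), stringsAsFactors = FALSE)
  df <- df[order(df$index), ]
  landmark_set(as.matrix(df[, c("x", "y", "z")]), subject_id = "template")
}

#' Per-expression landmark displacement fields
#'
#' For each of the six expressions, a 22 x 3 matrix of displacement
#' vectors (mm, at activation 1) added to the neutral template. The
#' directions encode the classic qualitative descriptions (surprise:
#' raised eyebrows, open jaw; anger: inner eyebrows pulled down and
#' together, pressed lips; ...); left/right displacements mirror each
#' other except for disgust, whose raised upper lip is deliberately
#' asymmetric. Magnitudes are generator calibration constants stored in
#' `extdata/expression_displacements.csv`.
#'
#' @return Named list of six 22 x 3 matrices (names `SU SA HA FE DI AN`).
#' @export
expression_displacements <- function() {
  df <- read.csv(extdata_path("expression_displacements.csv"),
                 stringsAsFactors = FALSE)
  out <- lapply(expression_levels(), function(e) {
    D <- matrix(0, 22, 3, dimnames = list(1:22, c("x", "y", "z")))
    sub <- df[df$expression == e, ]
    D[sub$landmark, ] <- as.matrix(sub[, c("dx", "dy", "dz")])
    D
  })
  setNames(out, expression_levels())
}

#' Synthetic dataset configuration
#'
#' @param n_per_class Faces generated per expression.
#' @param sigma Per-landmark, per-axis Gaussian measurement noise (mm).
#' @param sigma_id Identity shape jitter (mm): a second independent
#'   per-landmark Gaussian modeling between-subject variation.
#' @param activation_range Uniform range for the expression activation
#'   multiplier.
#' @param rot_z_deg,rot_xy_deg Maximum in-plane / out-of-plane rotation
#'   (degrees, uniform in +/- the bound). The out-of-plane bound is kept
#'   small because the 2D features assume near-frontal pose.
#' @param scale_range Uniform range of the global scale factor.
#' @param translation_mm Maximum absolute translation per axis.
#' @param seed RNG seed for [generate_dataset()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_class = 104L, sigma = 2, sigma_id = 1.5,
                             activation_range = c(0.6, 1.4),
                             rot_z_deg = 10, rot_xy_deg = 4,
                             scale_range = c(0.9, 1.1),
                             translation_mm = 20, seed = 1L) {
  stopifnot(n_per_class >= 1, sigma >= 0, sigma_id >= 0,
            length(activation_range) == 2, length(scale_range) == 2,
            all(scale_range > 0))
  structure(list(n_per_class = as.integer(n_per_class), sigma = sigma,
                 sigma_id = sigma_id, activation_range = activation_range,
                 rot_z_deg = rot_z_deg, rot_xy_deg = rot_xy_deg,
                 scale_range = scale_range, translation_mm = translation_mm,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Noise-free generator settings
#'
#' Convenience configuration with zero noise, zero jitter, activation
#' fixed at 1 and no similarity transform: under it every expression maps
#' to one deterministic geometry (the expression "signature").
#'
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
noise_free_config <- function(...) {
  synthetic_config(sigma = 0, sigma_id = 0, activation_range = c(1, 1),
                   rot_z_deg = 0, rot_xy_deg = 0, scale_range = c(1, 1),
                   translation_mm = 0, ...)
}

#' Generate one synthetic face
#'
#' Template + activation * expression displacement + identity jitter +
#' measurement noise, followed by a random global similarity transform.
#' Draws from the current RNG stream (seed it, or use
#' [generate_dataset()] which seeds once for the whole collection).
#'
#' @param expression Expression code (`SU SA HA FE DI AN`).
#' @param config A [synthetic_config()].
#' @param subject_id Identifier for the generated face.
#' @return A [landmark_set()].
#' @export
generate_face <- function(expression, config = synthetic_config(),
                          subject_id = "synthetic") {
  expression <- match.arg(expression, expression_levels())
  tpl <- neutral_template()$points
  disp <- expression_displacements()[[expression]]
  act <- runif(1, config$activation_range[1], config$activation_range[2])
  pts <- tpl + act * disp
  if (config$sigma_id > 0) pts <- pts + matrix(rnorm(66, 0, config$sigma_id), 22, 3)
  if (config$sigma > 0) pts <- pts + matrix(rnorm(66, 0, config$sigma), 22, 3)
  deg <- pi / 180
  R <- rotation_matrix(rx = runif(1, -1, 1) * config$rot_xy_deg * deg,
                       ry = runif(1, -1, 1) * config$rot_xy_deg * deg,
                       rz = runif(1, -1, 1) * config$rot_z_deg * deg)
  s <- runif(1, config$scale_range[1], config$scale_range[2])
  t <- runif(3, -1, 1) * config$translation_mm
  landmark_set(transform_points(pts, R, t, s),
               subject_id = subject_id, expression = expression)
}

#' Generate a labeled collection of synthetic faces
#'
#' `n_per_class` faces per expression, in class order `SU SA HA FE DI AN`
#' (104 per class, i.e. 624 faces, under the default balanced design).
#' Fixed seed gives a bit-identical collection. Serialize with
#' [write_landmarks_csv()] and extract features with
#' [extract_feature_matrix()].
#'
#' @param config A [synthetic_config()].
#' @param counts Optional named per-class counts overriding
#'   `n_per_class` (e.g. an unbalanced design).
#' @return List of [landmark_set()] objects.
#' @examples
#' faces <- generate_dataset(synthetic_config(n_per_class = 2, seed = 7))
#' length(faces)  # 12
#' @export
generate_dataset <- function(config = synthetic_config(), counts = NULL) {
  counts <- counts %||% setNames(rep(config$n_per_class, 6),
                                 expression_levels())
  stopifnot(all(names(counts) %in% expression_levels()))
  with_seed(config$seed, {
    out <- list()
    for (e in expression_levels()) {
      n <- if (e %in% names(counts)) counts[[e]] else 0L
      for (i in seq_len(n)) {
        out[[length(out) + 1L]] <-
          generate_face(e, config, subject_id = sprintf("%s_%03d", e, i))
      }
    }
    out
  })
}

# Class-signature matrix for the planted-feature mode: rows are the six
# expressions, columns the planted features; entries are the sign of the
# class offset. Six classes admit exactly ten distinct 3-vs-3
# bipartitions; the ten columns are those ten partitions, so no planted
# feature duplicates another's class information (not even up to sign).
planted_signature <- function(n_planted) {
  H <- rbind(
    SU = c(+1, +1, +1, +1, +1, +1, +1, +1, +1, +1),
    SA = c(+1, +1, +1, +1, -1, -1, -1, -1, -1, -1),
    HA = c(+1, -1, -1, -1, +1, +1, +1, -1, -1, -1),
    FE = c(-1, +1, -1, -1, +1, -1, -1, +1, +1, -1),
    DI = c(-1, -1, +1, -1, -1, +1, -1, +1, -1, +1),
    AN = c(-1, -1, -1, +1, -1, -1, +1, -1, +1, +1))
  if (n_planted > ncol(H)) stop("at most ", ncol(H), " planted features")
  H[, seq_len(n_planted), drop = FALSE]
}

#' Feature dataset with a planted informative subset
#'
#' Builds a feature matrix in which a chosen descriptor subset -- and only
#' it -- carries class signal, for selection-recovery experiments. Base
#' faces are expression-free template variations (identity jitter, noise,
#' similarity transform), so all 89 features have realistic values and
#' correlations but no class information; class-dependent offsets are then
#' added to the planted columns only. Offsets are `amplitude` times the
#' column's own standard deviation, signed per class by a fixed
#' class-signature matrix. Plants are applied in feature space (not by
#' displacing landmarks) because landmark displacements propagate to every
#' descriptor sharing a landmark and cannot isolate a subset.
#'
#' @param n_per_class Faces per expression.
#' @param planted_ids Descriptor ids to make informative (default: ten
#'   descriptors spread over the four feature groups).
#' @param amplitude Offset size in within-class standard deviations.
#' @param config Base-face generator settings (expression displacements
#'   are not applied).
#' @param seed RNG seed.
#' @return A `feature_matrix` with attribute `"planted_ids"`.
#' @export
planted_feature_dataset <- function(n_per_class = 60L,
                                    planted_ids = default_planted_ids(),
                                    amplitude = 0.7,
                                    config = synthetic_config(),
                                    seed = 1L) {
  cat89 <- feature_catalog()
  stopifnot(all(planted_ids %in% cat89$id))
  H <- planted_signature(length(planted_ids))
  with_seed(seed, {
    faces <- list()
    labs <- character(0)
    for (e in expression_levels()) {
      for (i in seq_len(n_per_class)) {
        faces[[length(faces) + 1L]] <-
          generate_face("SU", noise_off_expression(config),
                        subject_id = sprintf("%s_%03d", e, i))
        labs <- c(labs, e)
      }
    }
    fm <- extract_feature_matrix(faces)
    fm$y <- as_expression_factor(labs)
    cols <- match(planted_ids, cat89$id)
    sds <- apply(fm$X[, cols, drop = FALSE], 2, sd)
    for (j in seq_along(cols)) {
      fm$X[, cols[j]] <- fm$X[, cols[j]] +
        amplitude * sds[j] * H[as.integer(fm$y), j]
    }
    attr(fm, "planted_ids") <- planted_ids
    fm
  })
}

# strip the expression displacement from a config by generating "SU" faces
# with activation 0
noise_off_expression <- function(config) {
  config$activation_range <- c(0, 0)
  config
}

#' @rdname planted_feature_dataset
#' @export
default_planted_ids <- function() {
  c("1D3", "7D3", "19D3", "7A3", "10A3", "9D2", "15D2", "9A2", "16A2", "6D2")
}
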