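#' Canonical 22-landmark naming scheme
#'
#' The 22 anatomical points used for feature extraction, indexed 1--22:
#' eyebrows (1--6, outer/middle/inner left then inner/middle/outer right),
#' eye corners (7--10), nose saddle points (11--12), nose peaks and tip
#' (13--15), mouth corners (16, 18), outer/inner lip middles (17, 19--21)
#' and chin (22). Landmarks 8 and 9 are the inner eye corners; their
#' distance is the normalizer that makes all distance features scale-free.
#'
#' @return Character vector of length 22, named by canonical index.
#' @export
canonical_landmark_names <- function() {
  map <- read.csv(extdata_path("bosphorus_landmark_map.csv"),
                  stringsAsFactors = FALSE)
  map <- map[!is.na(map$canonical_index), ]
  setNames(map$name, map$canonical_index)[as.character(1:22)]
}

#' Construct a landmark set
#'
#' A `landmark_set` holds one face: exactly 22 canonical 3D points (in
#' millimetres or any consistent unit; all downstream features are
#' unit-free), a subject identifier and an optional expression label.
#' Coordinates follow a right-handed frontal convention: X to the subject's
#' image-right, Y upward, Z toward the camera.
#'
#' @param points Numeric 22 x 3 matrix of coordinates; row `i` is canonical
#'   landmark `i`, columns are x, y, z.
#' @param subject_id Character scalar identifying the face.
#' @param expression One of `"SU" "SA" "HA" "FE" "DI" "AN"`, or `NA` for
#'   neutral/unknown.
#' @return An object of class `landmark_set`.
#' @examples
#' tpl <- neutral_template()
#' tpl$points[8, ]  # inner left eye corner
#' @export
landmark_set <- function(points, subject_id = "unknown", expression = NA) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (!all(dim(points) == c(22, 3))) {
    stop("a landmark_set needs a 22 x 3 coordinate matrix, got ",
         paste(dim(points), collapse = " x "))
  }
  if (!all(is.finite(points))) {
    bad <- which(!is.finite(points), arr.ind = TRUE)
    stop("non-finite coordinate for landmark ", bad[1, 1])
  }
  dimnames(points) <- list(1:22, c("x", "y", "z"))
  obj <- structure(
    list(subject_id = as.character(subject_id),
         expression = if (length(expression) == 1 && is.na(expression)) {
           factor(NA, levels = expression_levels())
         } else {
           as_expression_factor(expression)
         },
         points = points),
    class = "landmark_set")
  if (euclidean_distance(points[8, ], points[9, ]) <= 0) {
    stop("landmarks 8 and 9 coincide: the inter-ocular normalizer would be zero")
  }
  obj
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> subject:", x$subject_id,
      " expression:", as.character(x$expression), "\n")
  cat("  22 landmarks, inter-ocular (8-9) distance:",
      format(euclidean_distance(x$points[8, ], x$points[9, ]), digits = 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.landmark_set <- function(x, ...) {
  data.frame(subject_id = x$subject_id,
             expression = as.character(x$expression),
             landmark_index = 1:22,
             x = x$points[, "x"], y = x$points[, "y"], z = x$points[, "z"],
             row.names = NULL)
}

# Apply a rigid/similarity transform: X -> scale * X R^T + t
transform_points <- function(points, rotation = diag(3), translation = c(0, 0, 0),
                             scale = 1) {
  sweep(scale * points %*% t(rotation), 2, -translation)
}

#' Apply a global similarity transform to a landmark set
#'
#' Rotates, scales and translates all 22 points identically. Used by the
#' synthetic generator for identity/pose variation and by the invariance
#' tests (3D features are unchanged under any such transform).
#'
#' @param ls A `landmark_set`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 numeric offset.
#' @param scale Positive scalar.
#' @return A transformed `landmark_set`.
#' @export
transform_landmarks <- function(ls, rotation = diag(3),
                                translation = c(0, 0, 0), scale = 1) {
  stopifnot(inherits(ls, "landmark_set"), scale > 0)
  landmark_set(transform_points(ls$points, rotation, translation, scale),
               subject_id = ls$subject_id, expression = ls$expression)
}

# Rotation matrices about the coordinate axes (angles in radians).
rotation_matrix <- function(rx = 0, ry = 0, rz = 0) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
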