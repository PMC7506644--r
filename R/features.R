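# Geometric primitives and feature extraction.

#' Euclidean distance between two points
#'
#' @param p,q Numeric coordinate vectors of equal length (2D or 3D).
#' @return Nonnegative scalar `||p - q||`.
#' @examples
#' euclidean_distance(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
euclidean_distance <- function(p, q) {
  stopifnot(length(p) == length(q), all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2))
}

#' Angle at a vertex defined by three points
#'
#' Computes `arccos` of the normalized dot product of the two arm vectors
#' `p1 - p2` and `p3 - p2`; `p2` is the vertex. The cosine is clamped to
#' `[-1, 1]` before `acos` so floating-point rounding can never produce
#' `NaN`. Works identically for 2D and 3D points.
#'
#' @param p1,p2,p3 Numeric coordinate vectors; `p2` is the vertex.
#' @return Angle in radians, in `[0, pi]`.
#' @examples
#' landmark_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # pi/2
#' @export
landmark_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("degenerate angle: vertex coincides with ",
         if (nu == 0) "the first arm point" else "the third arm point")
  }
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

#' Inter-ocular distance normalizer
#'
#' The 3D Euclidean distance between canonical landmarks 8 and 9 (inner
#' eye corners). Every distance feature -- 2D and 3D alike -- is divided
#' by this single quantity, which makes the feature vector invariant to
#' uniform scaling of the face.
#'
#' @param ls A [landmark_set()].
#' @return Positive scalar.
#' @export
normalizer <- function(ls) {
  stopifnot(inherits(ls, "landmark_set"))
  d <- euclidean_distance(ls$points[8, ], ls$points[9, ])
  if (d <= 0) stop("landmarks 8 and 9 coincide: normalizer is zero")
  d
}

#' Extract the geometric feature vector of one face
#'
#' Evaluates every catalog descriptor on a landmark set: distances are
#' Euclidean norms (on the X-Y projection for 2D descriptors) divided by
#' [normalizer()]; angles follow [landmark_angle()] (radians, never
#' normalized -- they are intrinsically scale-free). Output order is the
#' catalog order.
#'
#' @param ls A [landmark_set()].
#' @param catalog A [feature_catalog()] (defaults to the full 89).
#' @return Named numeric vector, one value per descriptor.
#' @examples
#' f <- extract_features(neutral_template())
#' length(f)  # 89
#' @export
extract_features <- function(ls, catalog = feature_catalog()) {
  stopifnot(inherits(ls, "landmark_set"))
  norm <- normalizer(ls)
  pts3 <- ls$points
  pts2 <- ls$points[, c("x", "y")]
  vals <- vapply(seq_len(nrow(catalog)), function(r) {
    pts <- if (catalog$space[r] == "3D") pts3 else pts2
    if (catalog$kind[r] == "distance") {
      euclidean_distance(pts[catalog$p1[r], ], pts[catalog$p2[r], ]) / norm
    } else {
      tryCatch(
        landmark_angle(pts[catalog$p1[r], ], pts[catalog$p2[r], ],
                       pts[catalog$p3[r], ]),
        error = function(e) stop("feature ", catalog$id[r], ": ",
                                 conditionMessage(e), call. = FALSE))
    }
  }, numeric(1))
  setNames(vals, catalog$id)
}

#' Build a feature matrix from a collection of faces
#'
#' @param sets List of [landmark_set()] objects (or a single one).
#' @param catalog A [feature_catalog()].
#' @return A `feature_matrix`: list with `X` (n x p numeric matrix, columns
#'   named by descriptor id), `y` (factor of expression labels, levels
#'   `SU SA HA FE DI AN`), `subject` (character) and `catalog`.
#' @export
extract_feature_matrix <- function(sets, catalog = feature_catalog()) {
  sets <- as_landmark_list(sets)
  X <- t(vapply(sets, extract_features, numeric(nrow(catalog)),
                catalog = catalog))
  feature_matrix(X,
                 y = vapply(sets, function(s) as.character(s$expression),
                            character(1)),
                 subject = vapply(sets, function(s) s$subject_id, character(1)),
                 catalog = catalog)
}

#' @rdname extract_feature_matrix
#' @param X Numeric matrix of feature values (columns in catalog order).
#' @param y Expression labels (or NA).
#' @param subject Subject identifiers.
#' @export
feature_matrix <- function(X, y = NULL, subject = NULL,
                           catalog = feature_catalog()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != nrow(catalog)) {
    stop("feature matrix has ", ncol(X), " columns but the catalog defines ",
         nrow(catalog))
  }
  colnames(X) <- catalog$id
  structure(list(X = X,
                 y = if (is.null(y)) NULL else as_expression_factor(y),
                 subject = subject %||% paste0("s", seq_len(nrow(X))),
                 catalog = catalog),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$X), " faces x ", ncol(x$X), " features\n",
      sep = "")
  if (!is.null(x$y)) print(table(x$y))
  invisible(x)
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  cbind(data.frame(subject_id = x$subject,
                   expression = if (is.null(x$y)) NA else as.character(x$y)),
        as.data.frame(x$X))
}

#' Read/write a feature matrix as CSV
#'
#' Header columns are `subject_id`, `expression`, then the descriptor ids
#' in catalog order. Values are written in full precision.
#'
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @param catalog Catalog used to validate the columns on read.
#' @return `read_features_csv` a `feature_matrix`; `write_features_csv`
#'   the path, invisibly.
#' @export
write_features_csv <- function(fm, path) {
  df <- as.data.frame(fm)
  for (col in fm$catalog$id) df[[col]] <- sprintf("%.17g", df[[col]])
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path, catalog = feature_catalog()) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(catalog$id %in% names(df))) {
    stop("feature CSV is missing descriptor columns, e.g. ",
         setdiff(catalog$id, names(df))[1])
  }
  feature_matrix(as.matrix(df[, catalog$id]),
                 y = if (all(is.na(df$expression))) NULL else df$expression,
                 subject = df$subject_id, catalog = catalog)
}

#' Mask the columns of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param mask Logical mask over catalog positions (see [mask_from_ids()]).
#' @return A `feature_matrix` restricted to the selected descriptors.
#' @export
mask_features <- function(fm, mask) {
  stopifnot(inherits(fm, "feature_matrix"))
  mask <- as.logical(mask)
  if (length(mask) != ncol(fm$X)) stop("mask length does not match features")
  sub <- fm$catalog[mask, ]
  rownames(sub) <- NULL
  class(sub) <- c("feature_catalog", "data.frame")
  structure(list(X = fm$X[, mask, drop = FALSE], y = fm$y,
                 subject = fm$subject, catalog = sub),
            class = "feature_matrix")
}
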