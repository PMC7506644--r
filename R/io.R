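# Landmark file input/output: Bosphorus-style name/coordinate records, a
# generic long-form CSV/JSON dialect, and the 51-point adaptation.

#' Bosphorus landmark-name mapping
#'
#' Mapping from the 24 landmark names of Bosphorus-style files to the 22
#' canonical indices. The two ear-lobe points carry no canonical index and
#' are ignored by the reader. Shipped as an editable CSV
#' (`extdata/bosphorus_landmark_map.csv`); pass a modified copy to
#' [read_bosphorus_landmarks()] to override.
#'
#' @return Data frame with columns `name` and `canonical_index` (NA = ignore).
#' @export
bosphorus_landmark_map <- function() {
  read.csv(extdata_path("bosphorus_landmark_map.csv"), stringsAsFactors = FALSE)
}

#' Read a Bosphorus-style landmark file
#'
#' File dialect: a free-text header line, a line with the number of
#' landmarks, then for each landmark a name line followed by a
#' whitespace-separated `x y z` line. Landmarks whose names are not in the
#' mapping (or map to NA, e.g. the ear lobes) are ignored; all 22 canonical
#' landmarks must be present.
#'
#' @param path Path to the file.
#' @param subject_id Subject identifier; defaults to the file name.
#' @param expression Expression code or `NA`.
#' @param map Name-to-index table, see [bosphorus_landmark_map()].
#' @return A [landmark_set()].
#' @export
read_bosphorus_landmarks <- function(path, subject_id = NULL, expression = NA,
                                     map = bosphorus_landmark_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("truncated landmark file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("line 2 of ", path, " must be the landmark count")
  if (length(lines) < 2 + 2 * n) {
    stop("file ", path, " declares ", n, " landmarks but is truncated")
  }
  pts <- matrix(NA_real_, 22, 3)
  for (i in seq_len(n)) {
    name_line <- 2 + 2 * i - 1
    coord_line <- 2 + 2 * i
    nm <- trimws(lines[name_line])
    xyz <- suppressWarnings(as.numeric(strsplit(trimws(lines[coord_line]),
                                                "\\s+")[[1]]))
    if (length(xyz) != 3 || anyNA(xyz)) {
      stop("malformed coordinate line ", coord_line, " in ", path,
           " (expected three numbers)")
    }
    idx <- map$canonical_index[match(nm, map$name)]
    if (length(idx) == 1 && !is.na(idx)) pts[idx, ] <- xyz
  }
  missing <- which(rowSums(is.na(pts)) > 0)
  if (length(missing)) {
    nms <- canonical_landmark_names()
    stop("canonical landmark(s) missing from ", path, ": ",
         paste(sprintf("%d (%s)", missing, nms[missing]), collapse = ", "))
  }
  landmark_set(pts,
               subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
               expression = expression)
}

#' Read/write landmark collections in the generic long-form dialect
#'
#' The generic CSV has one row per landmark with columns `subject_id`,
#' `expression`, `landmark_index`, `x`, `y`, `z`; the JSON equivalent is an
#' array of objects with fields `subject_id`, `expression` and a 22-row
#' `points` table. Coordinates are written with full `digits = 17`
#' precision so a write/read round trip is exact.
#'
#' @param sets A `landmark_set` or list of them.
#' @param path Output (input) file path.
#' @return `read_*` return a list of [landmark_set()] objects; `write_*`
#'   return `path` invisibly.
#' @export
write_landmarks_csv <- function(sets, path) {
  df <- do.call(rbind, lapply(as_landmark_list(sets), as.data.frame))
  # full precision so that read_landmarks_csv() is the exact inverse
  for (col in c("x", "y", "z")) df[[col]] <- sprintf("%.17g", df[[col]])
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "expression", "landmark_index", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("generic landmark CSV needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df[, c("subject_id", "landmark_index")])) {
    dup <- df[duplicated(df[, c("subject_id", "landmark_index")]), , drop = FALSE]
    stop("duplicate (subject_id, landmark_index) rows, first: ",
         dup$subject_id[1], " / ", dup$landmark_index[1])
  }
  split_sets(df)
}

#' @rdname write_landmarks_csv
#' @export
write_landmarks_json <- function(sets, path) {
  sets <- as_landmark_list(sets)
  payload <- lapply(sets, function(s) {
    list(subject_id = s$subject_id,
         expression = as.character(s$expression),
         points = as.data.frame(s)[, c("landmark_index", "x", "y", "z")])
  })
  # I(17) = 17 significant digits: exact double round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    pts <- payload$points[[i]]
    pts <- pts[order(pts$landmark_index), ]
    if (anyDuplicated(pts$landmark_index)) {
      stop("duplicate landmark_index for subject ", payload$subject_id[i])
    }
    landmark_set(as.matrix(pts[, c("x", "y", "z")]),
                 subject_id = payload$subject_id[i],
                 expression = payload$expression[i] %||% NA)
  })
}

as_landmark_list <- function(sets) {
  if (inherits(sets, "landmark_set")) return(list(sets))
  stopifnot(all(vapply(sets, inherits, TRUE, "landmark_set")))
  sets
}

split_sets <- function(df) {
  lapply(split(df, factor(df$subject_id, levels = unique(df$subject_id))),
         function(d) {
           d <- d[order(d$landmark_index), ]
           if (!identical(as.integer(d$landmark_index), 1:22)) {
             stop("subject ", d$subject_id[1],
                  ": expected landmark indices 1..22 exactly once")
           }
           landmark_set(as.matrix(d[, c("x", "y", "z")]),
                        subject_id = d$subject_id[1],
                        expression = d$expression[1])
         })
}

#' 51-point adaptation map
#'
#' Versioned default mapping from a 51-point facial landmark scheme (five
#' points per eyebrow, six per eye, nine on the nose, twenty on the mouth)
#' to the canonical 22-point scheme. Nineteen canonical points are direct
#' copies; three (the two nose saddle points and the chin middle) are
#' synthesized as midpoints of two documented donor points each, because
#' the 51-point scheme has no such landmarks. The table is an editable CSV
#' (`extdata/uibvfed_adaptation_map.csv`) and can be overridden.
#'
#' @return Data frame with columns `canonical_index`, `method`
#'   (`copy`/`midpoint`), `source1`, `source2`.
#' @export
uibvfed_adaptation_map <- function() {
  read.csv(extdata_path("uibvfed_adaptation_map.csv"), stringsAsFactors = FALSE)
}

#' Construct a raw 51-point landmark record
#'
#' @param points 51 x 3 numeric matrix with rownames giving point names
#'   (the naming used by [uibvfed_adaptation_map()]).
#' @param subject_id,expression As in [landmark_set()].
#' @return Object of class `raw_uibvfed_set`.
#' @export
uibvfed_set <- function(points, subject_id = "unknown", expression = NA) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) != 51 || ncol(points) != 3) {
    stop("a raw 51-point set needs a 51 x 3 matrix")
  }
  if (is.null(rownames(points))) stop("51-point matrix must have point names")
  structure(list(subject_id = as.character(subject_id),
                 expression = expression, points = points),
            class = "raw_uibvfed_set")
}

#' Adapt a 51-point landmark set to the canonical 22-point scheme
#'
#' Copies the 19 directly available canonical points and linearly
#' interpolates the remaining three as midpoints of their donor points
#' (see [uibvfed_adaptation_map()]). Interpolation is affine, so the
#' adaptation commutes with any global similarity transform of the input.
#'
#' @param raw A [uibvfed_set()].
#' @param map Adaptation table, defaults to the shipped constant.
#' @return A [landmark_set()].
#' @export
adapt_uibvfed <- function(raw, map = uibvfed_adaptation_map()) {
  stopifnot(inherits(raw, "raw_uibvfed_set"))
  pts <- matrix(NA_real_, 22, 3)
  for (r in seq_len(nrow(map))) {
    s1 <- raw$points[map$source1[r], ]
    if (anyNA(s1)) stop("source point missing: ", map$source1[r])
    if (map$method[r] == "copy") {
      pts[map$canonical_index[r], ] <- s1
    } else {
      s2 <- raw$points[map$source2[r], ]
      if (anyNA(s2)) stop("source point missing: ", map$source2[r])
      if (sqrt(sum((s1 - s2)^2)) == 0) {
        warning("coincident donor points for canonical landmark ",
                map$canonical_index[r])
      }
      pts[map$canonical_index[r], ] <- (s1 + s2) / 2
    }
  }
  landmark_set(pts, subject_id = raw$subject_id, expression = raw$expression)
}
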