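#' The 89-descriptor geometric feature catalog
#'
#' The full catalog of 89 geometric features: 19 normalized 3D distances
#' (`1D3`--`19D3`), 27 3D angles (`1A3`--`27A3`), 23 normalized 2D
#' distances (`1D2`--`23D2`) and 20 2D angles (`1A2`--`20A2`), in that
#' fixed column order. Each descriptor names two landmarks (distance) or
#' three (angle; the middle one is the vertex). 2D descriptors act on the
#' X-Y projection of the landmarks. The transcription lives in an editable
#' data file (`extdata/feature_catalog.csv`) so transcription errors
#' surface as count-invariant test failures rather than silent code bugs.
#'
#' @return A `feature_catalog`: data frame with columns `id`, `kind`
#'   (`distance`/`angle`), `space` (`3D`/`2D`), `p1`, `p2`, `p3`
#'   (`p3` is NA for distances; for angles `p2` is the vertex).
#' @examples
#' cat89 <- feature_catalog()
#' nrow(cat89)           # 89
#' table(cat89$kind, cat89$space)
#' @export
feature_catalog <- function() {
  df <- read.csv(extdata_path("feature_catalog.csv"), stringsAsFactors = FALSE)
  df$p3[df$p3 == ""] <- NA
  df$p3 <- as.integer(df$p3)
  validate_catalog(df)
  class(df) <- c("feature_catalog", "data.frame")
  df
}

validate_catalog <- function(df) {
  stopifnot(all(c("id", "kind", "space", "p1", "p2", "p3") %in% names(df)))
  if (anyDuplicated(df$id)) stop("duplicate descriptor ids in catalog")
  if (!all(df$kind %in% c("distance", "angle"))) stop("bad descriptor kind")
  if (!all(df$space %in% c("3D", "2D"))) stop("bad descriptor space")
  need3 <- df$kind == "angle"
  if (any(is.na(df$p3[need3]))) stop("angle descriptors need three landmarks")
  if (any(!is.na(df$p3[!need3]))) stop("distance descriptors take two landmarks")
  idx <- c(df$p1, df$p2, df$p3[need3])
  if (any(idx < 1 | idx > 22)) stop("landmark index outside 1..22 in catalog")
  invisible(df)
}

#' Count descriptors by group
#'
#' Tallies a catalog (or a masked subset of it) into the four groups used
#' throughout reporting: 3D angles, 3D distances, 2D angles, 2D distances.
#'
#' @param catalog A [feature_catalog()] or subset of one.
#' @return Named integer vector
#'   `c(angle_3d, distance_3d, angle_2d, distance_2d)`.
#' @export
catalog_group_counts <- function(catalog) {
  c(angle_3d = sum(catalog$kind == "angle" & catalog$space == "3D"),
    distance_3d = sum(catalog$kind == "distance" & catalog$space == "3D"),
    angle_2d = sum(catalog$kind == "angle" & catalog$space == "2D"),
    distance_2d = sum(catalog$kind == "distance" & catalog$space == "2D"))
}

#' The GA-selected 47-feature subset
#'
#' The published reduced feature set found by the wrapper genetic
#' algorithm: 47 of the 89 descriptors (14 3D angles, 12 3D distances,
#' 8 2D angles, 13 2D distances), shipped as a data file and exposed
#' either as a logical mask over the full catalog or as a sub-catalog.
#'
#' @return `ga_selected_mask()`: logical vector of length 89 aligned to
#'   [feature_catalog()] order, named by descriptor id.
#'   `ga_selected_catalog()`: the corresponding `feature_catalog` subset.
#' @export
ga_selected_mask <- function() {
  ids <- read.csv(extdata_path("ga_selected_ids.csv"),
                  stringsAsFactors = FALSE)$id
  cat89 <- feature_catalog()
  unknown <- setdiff(ids, cat89$id)
  if (length(unknown)) stop("selected ids not in catalog: ",
                            paste(unknown, collapse = ", "))
  setNames(cat89$id %in% ids, cat89$id)
}

#' @rdname ga_selected_mask
#' @export
ga_selected_catalog <- function() {
  cat89 <- feature_catalog()
  sub <- cat89[ga_selected_mask(), ]
  rownames(sub) <- NULL
  class(sub) <- c("feature_catalog", "data.frame")
  sub
}

#' Convert between masks and descriptor-id sets
#'
#' A feature mask is a logical (0/1) vector over the 89 catalog positions;
#' it is the genome of the genetic algorithm and the standard way to name
#' feature subsets across the package.
#'
#' @param ids Character vector of descriptor ids.
#' @param mask Logical or 0/1 numeric vector of length 89.
#' @param catalog The reference [feature_catalog()].
#' @return `mask_from_ids()` a named logical vector; `ids_from_mask()` a
#'   character vector of selected descriptor ids.
#' @export
mask_from_ids <- function(ids, catalog = feature_catalog()) {
  unknown <- setdiff(ids, catalog$id)
  if (length(unknown)) stop("unknown descriptor id(s): ",
                            paste(unknown, collapse = ", "))
  setNames(catalog$id %in% ids, catalog$id)
}

#' @rdname mask_from_ids
#' @export
ids_from_mask <- function(mask, catalog = feature_catalog()) {
  mask <- as.logical(mask)
  if (length(mask) != nrow(catalog)) {
    stop("mask length ", length(mask), " does not match catalog size ",
         nrow(catalog))
  }
  catalog$id[mask]
}
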