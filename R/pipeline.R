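# End-to-end orchestration: simulate/load -> extract -> balance -> select
# -> evaluate, with provenance and per-stage child seeds.

#' Feature-reduction accounting
#'
#' Compares a feature subset against the full catalog: descriptor counts
#' per group (3D angles, 3D distances, 2D angles, 2D distances) for both
#' sets and the percent reduction `100 * (1 - selected/original)` per
#' group and overall.
#'
#' @param catalog The full [feature_catalog()].
#' @param mask Logical mask of selected features (e.g.
#'   [ga_selected_mask()]).
#' @return Data frame with rows `angle_3d, distance_3d, angle_2d,
#'   distance_2d, total` and columns `original`, `selected`,
#'   `reduction_pct` (2 decimals, as conventionally reported) and
#'   `reduction_pct_raw` (full precision).
#' @examples
#' reduction_report(feature_catalog(), ga_selected_mask())
#' @export
reduction_report <- function(catalog = feature_catalog(),
                             mask = ga_selected_mask()) {
  mask <- as.logical(mask)
  if (length(mask) != nrow(catalog)) stop("mask length does not match catalog")
  orig <- catalog_group_counts(catalog)
  sel <- catalog_group_counts(catalog[mask, ])
  orig <- c(orig, total = sum(orig))
  sel <- c(sel, total = sum(sel))
  raw <- 100 * (1 - sel / orig)
  data.frame(group = names(orig),
             original = as.integer(orig),
             selected = as.integer(sel),
             reduction_pct = round(raw, 2),
             reduction_pct_raw = as.numeric(raw),
             row.names = NULL)
}

#' Run the full pipeline from a configuration
#'
#' Stages: obtain landmarks (simulate, or read a generic landmark CSV);
#' extract the 89 features; optionally SMOTE-balance; restrict to a
#' feature subset (full catalog, the published GA subset, a mask file, a
#' fresh GA run, or PCA scores); evaluate the chosen classifier with
#' repeated stratified 10-fold CV. All artifacts (features, mask, report,
#' confusion matrix, manifest) are written to `out_dir`; every random
#' stage draws its own child seed derived from `master_seed`, recorded in
#' the manifest, so an identical configuration reproduces identical
#' reports.
#'
#' @param config Nested list (or path to a YAML file with the same
#'   structure) with entries:
#'   * `input`: `list(source = "simulate", n_per_class, sigma, ...)` or
#'     `list(source = "generic", path = "faces.csv")`;
#'   * `features`: `"full"` (default), `"ga_published"`, a mask JSON path,
#'     `list(method = "ga", generations, population_size)`, or
#'     `list(method = "pca", variance_fraction)`;
#'   * `classifier`: one of `"svm3" "svm2" "knn1" "eknn"` (default
#'     `"svm3"`);
#'   * `balance_target`: per-class SMOTE target or `NULL`;
#'   * `repetitions`: CV repetitions (default 10);
#'   * `master_seed`: integer;
#'   * `out_dir`: output directory.
#' @return Invisibly, a list with the `report` (`cv_report`), the mask or
#'   PCA selection used, the `feature_matrix`, and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  master <- as.integer(config$master_seed %||% 1L)
  seeds <- list(simulate = child_seed(master, "simulate"),
                balance = child_seed(master, "balance"),
                select = child_seed(master, "select"),
                evaluate = child_seed(master, "evaluate"))

  stage <- "input"
  result <- tryCatch({
    input <- config$input %||% list(source = "simulate")
    faces <- switch(input$source %||% "simulate",
      simulate = {
        cfg <- synthetic_config(
          n_per_class = input$n_per_class %||% 104L,
          sigma = input$sigma %||% 2,
          seed = seeds$simulate)
        generate_dataset(cfg)
      },
      generic = read_landmarks_csv(input$path),
      stop("unknown input source: ", input$source))

    stage <- "extract"
    fm <- extract_feature_matrix(faces)
    write_features_csv(fm, file.path(out_dir, "features.csv"))

    stage <- "balance"
    if (!is.null(config$balance_target)) {
      fm <- smote_balance(fm, target_per_class = config$balance_target,
                          seed = seeds$balance)
    }

    stage <- "select"
    fsel <- config$features %||% "full"
    selection <- NULL
    mask <- NULL
    if (identical(fsel, "full")) {
      mask <- rep(TRUE, ncol(fm$X))
    } else if (identical(fsel, "ga_published")) {
      mask <- ga_selected_mask()
    } else if (is.character(fsel)) {
      mj <- jsonlite::read_json(fsel, simplifyVector = TRUE)
      mask <- mask_from_ids(mj$selected_ids, fm$catalog)
    } else if (identical(fsel$method, "ga")) {
      cfg <- ga_config(
        population_size = fsel$population_size %||% 20L,
        generations = fsel$generations %||% 250L,
        rng_seed = seeds$select, cv_seed = seeds$select)
      selection <- ga_select(fm, config = cfg)
      mask <- selection$best_mask
    } else if (identical(fsel$method, "pca")) {
      selection <- pca_select(fm, fsel$variance_fraction %||% 0.99)
    } else {
      stop("unrecognized feature selection setting")
    }

    eval_input <- if (inherits(selection, "pca_selection")) {
      list(X = selection$scores, y = fm$y)
    } else {
      masked <- mask_features(fm, mask)
      list(X = masked$X, y = masked$y)
    }
    if (!is.null(mask)) {
      write_mask_json(mask, fm$catalog, file.path(out_dir, "mask.json"))
      rr <- reduction_report(fm$catalog, mask)
      write.csv(rr, file.path(out_dir, "reduction_report.csv"),
                row.names = FALSE)
    }

    stage <- "evaluate"
    spec <- switch(config$classifier %||% "svm3",
                   svm3 = svm3(), svm2 = svm2(), knn1 = knn1(),
                   eknn = eknn(seed = seeds$evaluate),
                   stop("unknown classifier: ", config$classifier))
    report <- evaluate(spec, eval_input$X, eval_input$y,
                       n_repetitions = config$repetitions %||% 10L,
                       seed = seeds$evaluate)
    write_cv_report(report, file.path(out_dir, "report.json"))
    write.csv(round(report$confusion, 6),
              file.path(out_dir, "confusion.csv"))

    manifest <- list(package_version = as.character(utils::packageVersion("geomexpr")),
                     config = config, master_seed = master,
                     child_seeds = seeds,
                     n_faces = nrow(fm$X),
                     n_features_evaluated = ncol(eval_input$X),
                     catalog_size = nrow(fm$catalog))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    list(report = report, mask = mask, selection = selection,
         features = fm, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

write_mask_json <- function(mask, catalog, path) {
  jsonlite::write_json(
    list(catalog_size = nrow(catalog),
         bits = paste(as.integer(mask), collapse = ""),
         selected_ids = catalog$id[as.logical(mask)]),
    path, auto_unbox = TRUE)
  invisible(path)
}
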