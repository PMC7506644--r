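# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. All exported stochastic functions route
# their randomness through this so a user seed never clobbers the session.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded child seed from a master seed and a stage label so each
# pipeline stage gets its own reproducible stream.
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.integer(master) * 1009L + as.integer(h)) %% .Machine$integer.max)
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "geomexpr", mustWork = FALSE)
  if (!nzchar(path)) {
    # during in-source testing without installation
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("cannot locate bundled data file: ", file)
  path
}

as_expression_factor <- function(x) {
  lv <- expression_levels()
  if (is.factor(x)) x <- as.character(x)
  bad <- !is.na(x) & !x %in% lv
  if (any(bad)) {
    stop("unknown expression code(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected ", paste(lv, collapse = ", "), ")")
  }
  factor(x, levels = lv)
}

# Accept either a feature_matrix or an explicit (X, y) pair.
as_xy <- function(x, y = NULL) {
  if (inherits(x, "feature_matrix")) {
    list(X = x$X, y = x$y, subject = x$subject)
  } else {
    X <- as.matrix(x)
    storage.mode(X) <- "double"
    list(X = X, y = if (is.null(y)) NULL else factor(y), subject = rownames(X))
  }
}
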