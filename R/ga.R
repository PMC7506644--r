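# Wrapper feature selection by genetic algorithm.

#' Genetic algorithm configuration
#'
#' Defaults follow the published setup: population of 20 binary
#' chromosomes of 89 genes, 250 generations, tournament parent selection
#' (best two out of five randomly chosen individuals), one-point
#' crossover, per-gene bit-flip mutation, and elitism carrying the
#' all-time best individual into every generation. The mutation rate is
#' the canonical `1/m` per gene (the source setup says only "simple"
#' mutation).
#'
#' @param population_size Even integer >= 2.
#' @param generations Number of generational updates.
#' @param tournament_pool Individuals drawn (without replacement) per
#'   tournament.
#' @param parents_per_tournament Parents kept per tournament (the best 2).
#' @param mutation_rate Per-gene flip probability in (0, 1); `NULL` means
#'   `1/n_genes`, resolved when the run starts.
#' @param elitism Number of elite individuals preserved (1).
#' @param rng_seed Seed for initialization, tournaments, crossover cuts
#'   and mutation.
#' @param cv_seed Seed fixing the fitness cross-validation folds for the
#'   whole run (selection pressure should not be fold noise).
#' @param cost,degree SVM fitness parameters, see [fitness()].
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 20L, generations = 250L,
                      tournament_pool = 5L, parents_per_tournament = 2L,
                      mutation_rate = NULL, elitism = 1L,
                      rng_seed = 1L, cv_seed = 1L, cost = 1, degree = 3L) {
  stopifnot(population_size >= 2, population_size %% 2 == 0,
            generations >= 1, tournament_pool >= parents_per_tournament,
            parents_per_tournament == 2L, elitism == 1L,
            is.null(mutation_rate) ||
              (mutation_rate > 0 && mutation_rate < 1))
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 tournament_pool = as.integer(tournament_pool),
                 parents_per_tournament = as.integer(parents_per_tournament),
                 mutation_rate = mutation_rate, elitism = as.integer(elitism),
                 rng_seed = as.integer(rng_seed), cv_seed = as.integer(cv_seed),
                 cost = cost, degree = as.integer(degree)),
            class = "ga_config")
}

#' One-point crossover of two binary chromosomes
#'
#' Splices the parents at a cut position `cut` in `1..m-1`: the first
#' child takes genes `1..cut` from `a` and the rest from `b`; the second
#' child is the complement.
#'
#' @param a,b Logical/0-1 vectors of equal length.
#' @param cut Integer cut point.
#' @return List of two children.
#' @export
one_point_crossover <- function(a, b, cut) {
  m <- length(a)
  stopifnot(length(b) == m, cut >= 1, cut <= m - 1)
  list(c(a[seq_len(cut)], b[(cut + 1):m]),
       c(b[seq_len(cut)], a[(cut + 1):m]))
}

mutate_mask <- function(mask, rate) {
  flip <- runif(length(mask)) < rate
  xor(mask, flip)
}

#' Select features with a wrapper genetic algorithm
#'
#' Runs the generational loop: uniform random initialization; per
#' generation, repeat \{draw `tournament_pool` distinct individuals, keep
#' the best two as parents, one-point crossover at a uniform cut,
#' per-gene bit-flip mutation\} until `population_size` offspring exist;
#' evaluate all offspring with [fitness()]; then elitism copies the
#' all-time best individual over the worst offspring. The result is the
#' best individual seen in any generation, so the recorded best-fitness
#' history is nondecreasing by construction.
#'
#' Identical data and configuration (both seeds included) give
#' bit-identical results.
#'
#' @param x A `feature_matrix` or numeric matrix.
#' @param y Labels (if `x` is a matrix).
#' @param config A [ga_config()].
#' @param verbose Print per-generation progress.
#' @return A `ga_result`: list with `best_mask` (named logical),
#'   `best_fitness` (percent), `fitness_history` (per generation, best so
#'   far), `mean_history` (population mean per generation),
#'   `generation_of_convergence` (first generation attaining the final
#'   best), `n_evaluations`, and the `config`.
#' @export
ga_select <- function(x, y = NULL, config = ga_config(), verbose = FALSE) {
  d <- as_xy(x, y)
  if (is.null(d$y)) stop("class labels are required")
  m <- ncol(d$X)
  rate <- config$mutation_rate %||% (1 / m)
  ids <- colnames(d$X) %||% paste0("f", seq_len(m))

  # folds and the standardized matrix are fixed for the entire run
  fold <- content_folds(d$X, d$y, 10L, seed = config$cv_seed)
  Zfull <- standardize_columns(d$X)
  yi <- as.integer(d$y)
  ncl <- nlevels(d$y)

  cache <- new.env(hash = TRUE, parent = emptyenv())
  n_eval <- 0L
  eval_mask <- function(mask) {
    if (!any(mask)) return(0)
    key <- rawToChar(as.raw(45L + mask))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- cpp_svm_ovo_cv(Zfull[, mask, drop = FALSE], yi, fold, ncl,
                          cost = config$cost, degree = config$degree,
                          gamma = 1 / sum(mask))
    n_eval <<- n_eval + 1L
    cache[[key]] <- val
    val
  }

  with_seed(config$rng_seed, {
    pop <- lapply(seq_len(config$population_size),
                  function(i) runif(m) < 0.5)
    fit <- vapply(pop, eval_mask, numeric(1))

    best_i <- which.max(fit)
    best_mask <- pop[[best_i]]
    best_fit <- fit[best_i]
    history <- numeric(config$generations + 1L)
    mean_hist <- numeric(config$generations + 1L)
    history[1] <- best_fit
    mean_hist[1] <- mean(fit)

    for (gen in seq_len(config$generations)) {
      offspring <- vector("list", config$population_size)
      k <- 0L
      while (k < config$population_size) {
        pool <- sample(config$population_size, config$tournament_pool)
        parents <- pool[order(fit[pool], decreasing = TRUE)[1:2]]
        cut <- sample.int(m - 1L, 1L)
        children <- one_point_crossover(pop[[parents[1]]], pop[[parents[2]]],
                                        cut)
        for (ch in children) {
          if (k < config$population_size) {
            k <- k + 1L
            offspring[[k]] <- mutate_mask(ch, rate)
          }
        }
      }
      off_fit <- vapply(offspring, eval_mask, numeric(1))

      # elitism: the all-time best replaces the worst offspring
      worst <- which.min(off_fit)
      offspring[[worst]] <- best_mask
      off_fit[worst] <- best_fit

      pop <- offspring
      fit <- off_fit
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_fit) {
        best_fit <- fit[gen_best]
        best_mask <- pop[[gen_best]]
      }
      history[gen + 1L] <- best_fit
      mean_hist[gen + 1L] <- mean(fit)
      if (verbose) {
        cat(sprintf("generation %3d  best %6.2f  mean %6.2f  evals %d\n",
                    gen, best_fit, mean(fit), n_eval))
      }
    }

    structure(list(best_mask = setNames(best_mask, ids),
                   best_fitness = best_fit,
                   fitness_history = history,
                   mean_history = mean_hist,
                   generation_of_convergence =
                     which(history == best_fit)[1] - 1L,
                   n_evaluations = n_eval,
                   config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> best fitness ", sprintf("%.2f%%", x$best_fitness),
      " with ", sum(x$best_mask), "/", length(x$best_mask), " features\n",
      "  converged at generation ", x$generation_of_convergence,
      " (", x$n_evaluations, " unique fitness evaluations)\n", sep = "")
  invisible(x)
}

#' Repeated GA runs over a seed set
#'
#' Convenience loop reproducing the best/worst-of-30 protocol: runs
#' [ga_select()] once per seed and reports the runs ordered by final
#' fitness.
#'
#' @param x,y Data as in [ga_select()].
#' @param seeds Integer vector of `rng_seed` values, one run each.
#' @param config Base [ga_config()]; its `rng_seed` is replaced per run.
#' @return List with `runs` (all `ga_result`s), `best`, `worst`.
#' @export
ga_replicate <- function(x, y = NULL, seeds = 1:30, config = ga_config()) {
  runs <- lapply(seeds, function(s) {
    cfg <- config
    cfg$rng_seed <- as.integer(s)
    ga_select(x, y, cfg)
  })
  fits <- vapply(runs, function(r) r$best_fitness, numeric(1))
  list(runs = runs, seeds = seeds,
       best = runs[[which.max(fits)]], worst = runs[[which.min(fits)]])
}
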