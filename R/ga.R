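#' Genetic-algorithm configuration
#'
#' Settings for scorecard refinement. The fitness of a candidate score
#' vector is `w1 * AUC + w2 * R`, where AUC measures how well the
#' weighted-sum scores separate the classes on the training set
#' (cross-validated by default) and R is the Pearson correlation between
#' the candidate and the initial scorecard, anchoring the refined card to
#' its interpretable starting point. Default weights are 0.9 and 0.1.
#'
#' The GA is a standard real-valued scheme: individuals are full score
#' vectors initialized as the initial card plus Gaussian noise (one
#' individual kept as the exact initial card), tournament selection,
#' uniform crossover, per-gene Gaussian mutation, elitism, and clipping to
#' the 0-1000 scale after every generation.
#'
#' @param population_size Individuals per generation (default 100).
#' @param generations Number of generations (default 50; 0 fits only the
#'   threshold).
#' @param crossover_rate Probability a selected pair undergoes uniform
#'   crossover (default 0.8).
#' @param mutation_rate Per-gene mutation probability (default 0.05).
#' @param mutation_sigma Gaussian mutation step on the 0-1000 score scale
#'   (default 50).
#' @param elitism_count Top individuals copied unchanged into the next
#'   generation (default 1; must be < population_size).
#' @param tournament_size Tournament selection size (default 3).
#' @param w1,w2 Fitness weights for AUC and correlation (defaults 0.9, 0.1).
#' @param cv_folds Folds for the cross-validated fitness AUC (default 10).
#' @param auc_method `"cv"` (stratified k-fold mean, the default) or
#'   `"full"` (single full-training-set AUC, markedly faster).
#' @param seed Master seed deriving fold assignment, GA initialization and
#'   per-run seeds.
#' @param n_runs Independent GA restarts for [multirun_optimize()]
#'   (default 10).
#' @return A list of class `fscm_ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 50L,
                      crossover_rate = 0.8, mutation_rate = 0.05,
                      mutation_sigma = 50, elitism_count = 1L,
                      tournament_size = 3L, w1 = 0.9, w2 = 0.1,
                      cv_folds = 10L, auc_method = c("cv", "full"),
                      seed = 1L, n_runs = 10L) {
  auc_method <- match.arg(auc_method)
  if (population_size < 2L) {
    stop("population_size must be at least 2.", call. = FALSE)
  }
  if (elitism_count < 1L || elitism_count >= population_size) {
    stop("elitism_count must satisfy 1 <= elitism_count < population_size.",
         call. = FALSE)
  }
  if (cv_folds < 2L) stop("cv_folds must be at least 2.", call. = FALSE)
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         mutation_sigma = mutation_sigma,
         elitism_count = as.integer(elitism_count),
         tournament_size = as.integer(tournament_size),
         w1 = w1, w2 = w2, cv_folds = as.integer(cv_folds),
         auc_method = auc_method, seed = as.integer(seed),
         n_runs = as.integer(n_runs)),
    class = "fscm_ga_config"
  )
}

#' @export
print.fscm_ga_config <- function(x, ...) {
  cat(sprintf(
    paste0("<fscm_ga_config> pop %d x %d generations | fitness %.2g*AUC",
           " (%s) + %.2g*R | seed %d\n"),
    x$population_size, x$generations, x$w1, x$auc_method, x$w2, x$seed))
  invisible(x)
}

#' Scorecard fitness: weighted AUC plus correlation to the initial card
#'
#' @param candidate Numeric score vector (canonical order) to assess.
#' @param init Initial score vector of the same dimension.
#' @param peptides Labeled training tibble.
#' @param region Region name or spec.
#' @param config A [ga_config()].
#' @param junction NC junction convention.
#' @return `w1 * AUC + w2 * R`. A constant candidate has undefined
#'   correlation; R is taken as 0 with a warning.
#' @export
scorecard_fitness <- function(candidate, init, peptides, region,
                              config = ga_config(),
                              junction = c("include", "exclude")) {
  junction <- match.arg(junction)
  region <- region_spec(region)
  stopifnot(length(candidate) == length(init))
  auc <- if (config$auc_method == "cv") {
    cv_auc(stats::setNames(candidate, canonical_symbols(region$granularity)),
           peptides, region, folds = config$cv_folds, seed = config$seed,
           junction = junction)
  } else {
    mat <- composition_matrix(peptides, region, junction = junction)
    keep <- !seq_len(nrow(mat)) %in% attr(mat, "unscorable")
    roc_auc(as.vector(mat[keep, , drop = FALSE] %*% candidate),
            peptides$label[keep])$auc
  }
  r <- safe_pearson(candidate, init)
  config$w1 * auc + config$w2 * r
}

# Pearson correlation with the undefined (constant-vector) case mapped to 0
safe_pearson <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Constant score vector: correlation undefined, using 0.",
            call. = FALSE)
    return(0)
  }
  stats::cor(x, y)
}

#' Refine a scorecard by genetic algorithm
#'
#' Evolves the 400 (or 20) propensity scores under the AUC+correlation
#' fitness, starting from the initial card. Elitism guarantees a
#' non-decreasing best-fitness trace; all scores are clipped to the 0-1000
#' scale after every generation. The decision threshold is fitted post hoc
#' on the training scores of the best individual. Deterministic for a
#' fixed `config$seed`.
#'
#' @param init_card An `fscm_scorecard` (normally provenance `"initial"`).
#' @param peptides Labeled training tibble.
#' @param config A [ga_config()].
#' @param junction NC junction convention.
#' @return An object of class `fscm_optimization`: `best_card`
#'   (provenance `"optimized"`, threshold set), `fitness_trace`
#'   (per-generation best fitness, non-decreasing), `final_auc`,
#'   `final_correlation`, `fitness`, `run_seed`.
#' @export
optimize_scorecard <- function(init_card, peptides, config = ga_config(),
                               junction = c("include", "exclude")) {
  junction <- match.arg(junction)
  stopifnot(inherits(init_card, "fscm_scorecard"))
  region <- init_card$region
  init <- unname(init_card$scores)
  n_genes <- length(init)

  # the composition matrix is fixed across the whole run; fitness of a
  # population is then one matrix product plus per-column AUC/cor
  mat <- composition_matrix(peptides, region, junction = junction)
  keep <- !seq_len(nrow(mat)) %in% attr(mat, "unscorable")
  x <- mat[keep, , drop = FALSE]
  labels <- peptides$label[keep]
  fold_id <- stratified_folds(labels, config$cv_folds, config$seed)

  pop_auc <- function(scores_mat) {
    s <- x %*% scores_mat
    if (config$auc_method == "full") {
      return(apply(s, 2L, function(col) roc_auc(col, labels)$auc))
    }
    apply(s, 2L, function(col) {
      aucs <- vapply(seq_len(config$cv_folds), function(k) {
        lab <- labels[fold_id == k]
        if (!all(c("positive", "negative") %in% lab)) return(NA_real_)
        roc_auc(col[fold_id == k], lab)$auc
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    })
  }
  pop_fitness <- function(scores_mat) {
    auc <- pop_auc(scores_mat)
    r <- apply(scores_mat, 2L, function(col) {
      if (stats::sd(col) == 0) 0 else stats::cor(col, init)
    })
    list(fitness = config$w1 * auc + config$w2 * r, auc = auc, r = r)
  }

  result <- withr::with_seed(config$seed, if (config$generations == 0L) {
    # no evolution: keep the initial card, only the threshold is fitted
    fit0 <- pop_fitness(matrix(init, ncol = 1L))
    list(best = list(genes = init, fitness = fit0$fitness[1L],
                     auc = fit0$auc[1L], r = fit0$r[1L]),
         trace = fit0$fitness[1L])
  } else {
    pop <- matrix(stats::rnorm(n_genes * config$population_size, mean = init,
                               sd = config$mutation_sigma),
                  nrow = n_genes)
    pop[, 1L] <- init # one exact copy of the initial card
    pop <- pmin(pmax(pop, 0), 1000)
    fit <- pop_fitness(pop)
    trace <- numeric(config$generations + 1L)
    best_i <- which.max(fit$fitness)
    best <- list(genes = pop[, best_i], fitness = fit$fitness[best_i],
                 auc = fit$auc[best_i], r = fit$r[best_i])
    trace[1L] <- best$fitness

    for (gen in seq_len(config$generations)) {
      elite_idx <- order(fit$fitness, decreasing = TRUE)[
        seq_len(config$elitism_count)]
      n_children <- config$population_size - config$elitism_count
      tournament <- function() {
        contenders <- sample.int(config$population_size,
                                 config$tournament_size, replace = TRUE)
        contenders[which.max(fit$fitness[contenders])]
      }
      children <- matrix(0, nrow = n_genes, ncol = n_children)
      for (j in seq_len(n_children)) {
        p1 <- pop[, tournament()]
        p2 <- pop[, tournament()]
        child <- if (stats::runif(1) < config$crossover_rate) {
          ifelse(stats::runif(n_genes) < 0.5, p1, p2)
        } else {
          p1
        }
        mutate_mask <- stats::runif(n_genes) < config$mutation_rate
        child[mutate_mask] <- child[mutate_mask] +
          stats::rnorm(sum(mutate_mask), sd = config$mutation_sigma)
        children[, j] <- child
      }
      pop <- cbind(pop[, elite_idx, drop = FALSE], children)
      pop <- pmin(pmax(pop, 0), 1000)
      fit <- pop_fitness(pop)
      gen_best <- which.max(fit$fitness)
      if (fit$fitness[gen_best] > best$fitness) {
        best <- list(genes = pop[, gen_best],
                     fitness = fit$fitness[gen_best],
                     auc = fit$auc[gen_best], r = fit$r[gen_best])
      }
      trace[gen + 1L] <- best$fitness
    }
    list(best = best, trace = trace)
  })


  best_card <- new_scorecard(
    stats::setNames(result$best$genes, names(init_card$scores)),
    region, provenance = "optimized",
    metadata = c(init_card$metadata,
                 list(seed = config$seed,
                      generations = config$generations,
                      population_size = config$population_size,
                      auc_method = config$auc_method)))
  train_scores <- as.vector(x %*% result$best$genes)
  best_card$threshold <- select_threshold(train_scores, labels)

  structure(
    list(best_card = best_card,
         fitness_trace = result$trace,
         fitness = result$best$fitness,
         final_auc = result$best$auc,
         final_correlation = result$best$r,
         run_seed = config$seed,
         config = config),
    class = "fscm_optimization"
  )
}

#' @export
print.fscm_optimization <- function(x, ...) {
  cat(sprintf(
    paste0("<fscm_optimization> %s | fitness %.4f (AUC %.4f, R %.4f) ",
           "after %d generations, seed %d\n"),
    x$best_card$region$name, x$fitness, x$final_auc, x$final_correlation,
    length(x$fitness_trace) - 1L, x$run_seed))
  invisible(x)
}

#' @export
tidy.fscm_optimization <- function(x, ...) {
  tibble::tibble(
    generation = seq_along(x$fitness_trace) - 1L,
    best_fitness = x$fitness_trace
  )
}

#' @export
glance.fscm_optimization <- function(x, ...) {
  tibble::tibble(
    fitness = x$fitness,
    auc = x$final_auc,
    correlation = x$final_correlation,
    threshold = x$best_card$threshold,
    generations = length(x$fitness_trace) - 1L,
    run_seed = x$run_seed
  )
}

#' Multiple independent GA runs, best selected
#'
#' Runs the genetic algorithm `config$n_runs` times with derived seeds
#' (`seed + run index`) and flags the run with the highest fitness as
#' selected, mirroring the practice of generating several refined
#' scorecards and keeping the best.
#'
#' @inheritParams optimize_scorecard
#' @return A list with `runs` (all `fscm_optimization` objects),
#'   `selected` (index of the best run) and `best` (the selected run).
#' @export
multirun_optimize <- function(init_card, peptides, config = ga_config(),
                              junction = c("include", "exclude")) {
  junction <- match.arg(junction)
  stopifnot(config$n_runs >= 1L)
  runs <- lapply(seq_len(config$n_runs), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    optimize_scorecard(init_card, peptides, cfg, junction = junction)
  })
  fitnesses <- vapply(runs, function(r) r$fitness, numeric(1))
  selected <- which.max(fitnesses)
  list(runs = runs, selected = selected, best = runs[[selected]])
}
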