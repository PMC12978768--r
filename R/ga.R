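# Genetic-algorithm selection of the descriptor subset minimizing LOO-PRESS,
# with an exhaustive-search oracle for small instances. Chromosomes are
# fixed-cardinality index sets (the subset size is a modelling constraint,
# not an objective); uniform crossover with repair, per-gene mutation to an
# unused index, tournament selection of size 2, and elitism of 1.

#' GA configuration
#'
#' Defaults mirror the reference configuration (population 500,
#' 500 generations, crossover probability 0.5, mutation probability 0.01,
#' subset size 12); test-scale runs shrink the budget through these fields.
#'
#' @param population_size,generations,crossover_prob,mutation_prob GA
#'   operator settings.
#' @param subset_size cardinality N of every chromosome.
#' @param tournament_size,elitism selection settings.
#' @param seed integer seed (required; the run is fully reproducible).
#' @param early_stop_patience stop after this many generations without
#'   improvement (NULL = never).
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 500, generations = 500,
                      crossover_prob = 0.5, mutation_prob = 0.01,
                      subset_size = 12, tournament_size = 2, elitism = 1,
                      seed, early_stop_patience = NULL) {
  if (missing(seed)) stop("seed is required")
  stopifnot(population_size >= 2, generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            subset_size >= 1, tournament_size >= 1, elitism >= 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 subset_size = as.integer(subset_size),
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 seed = as.integer(seed),
                 early_stop_patience = early_stop_patience),
            class = "ga_config")
}

#' LOO-PRESS fitness of a descriptor subset
#'
#' The fitness of a subset is the leave-one-out PRESS of the activity model
#' restricted to it (lower is better). Results are memoized per canonical
#' (sorted) subset inside `cache`.
#'
#' @param subset integer descriptor indices (no duplicates).
#' @param data an `ecga_data`.
#' @param cache environment used for memoization (optional).
#' @param ... passed to [loo_predictions()] (e.g. `A0`, `T`).
#' @return scalar PRESS.
#' @export
ga_fitness <- function(subset, data, cache = NULL, ...) {
  if (anyDuplicated(subset)) stop("duplicate indices in subset")
  key <- paste(sort(subset), collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  pt <- suppressWarnings(loo_predictions(data, sort(subset), ...))
  val <- press(pt$A_exp, pt$A_calc)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Genetic-algorithm descriptor-subset search
#'
#' Evolves fixed-cardinality index sets under LOO-PRESS fitness. Uniform
#' crossover pools the two parents' indices and repairs to cardinality N
#' (deduplicate, refill randomly from unused indices); mutation replaces an
#' index with a random unused one at `mutation_prob` per gene; tournament
#' selection (size 2) and elitism (best individual carried over) complete
#' the loop. Identical seeds give identical results including the trace.
#'
#' @param data an `ecga_data`.
#' @param config a [ga_config()].
#' @param p total number of descriptors (default: taken from `data`).
#' @param ... passed to the fitness evaluations (e.g. `A0`, `T`).
#' @return list of class `ga_result`: `best_subset`, `best_fitness`,
#'   `fitness_trace` (per-generation best/mean), `evaluations`, `seed`.
#' @export
ga_search <- function(data, config, p = NULL, ...) {
  stopifnot(inherits(config, "ga_config"))
  if (is.null(p)) p <- length(attr(data, "descriptor_names"))
  N <- config$subset_size
  if (p < N) stop("infeasible config: fewer descriptors than subset_size")
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  fit1 <- function(subset) {
    key <- paste(sort(subset), collapse = ",")
    if (is.null(cache[[key]])) evals <<- evals + 1L
    ga_fitness(subset, data, cache = cache, ...)
  }

  if (p == N) {
    subset <- seq_len(p)
    f <- fit1(subset)
    return(structure(list(best_subset = subset, best_fitness = f,
                          fitness_trace = data.frame(generation = 0L,
                                                     best = f, mean = f),
                          evaluations = evals, seed = config$seed),
                     class = "ga_result"))
  }

  set.seed(config$seed)
  pop <- replicate(config$population_size, sort(sample.int(p, N)),
                   simplify = FALSE)
  fitness <- vapply(pop, fit1, 0)
  trace <- data.frame(generation = 0L, best = min(fitness), mean = mean(fitness))
  best_idx <- which.min(fitness)
  best_subset <- pop[[best_idx]]; best_fit <- fitness[best_idx]
  stagnant <- 0L

  repair <- function(pool) {
    pool <- unique(pool)
    if (length(pool) > N) {
      pool <- sample(pool, N)
    } else if (length(pool) < N) {
      pool <- c(pool, sample(setdiff(seq_len(p), pool), N - length(pool)))
    }
    sort(pool)
  }
  mutate <- function(chrom) {
    hit <- stats::runif(N) < config$mutation_prob
    if (any(hit)) {
      unused <- setdiff(seq_len(p), chrom)
      for (g in which(hit)) {
        if (length(unused) == 0L) break
        pick <- if (length(unused) == 1L) unused else sample(unused, 1)
        unused <- c(setdiff(unused, pick), chrom[g])
        chrom[g] <- pick
      }
    }
    sort(chrom)
  }
  tournament <- function() {
    ix <- sample.int(config$population_size, config$tournament_size)
    ix[which.min(fitness[ix])]
  }

  for (gen in seq_len(config$generations)) {
    newpop <- vector("list", config$population_size)
    k <- 0L
    if (config$elitism > 0L) {
      ord <- order(fitness)[seq_len(config$elitism)]
      for (i in ord) { k <- k + 1L; newpop[[k]] <- pop[[i]] }
    }
    while (k < config$population_size) {
      p1 <- pop[[tournament()]]; p2 <- pop[[tournament()]]
      child <- if (stats::runif(1) < config$crossover_prob) {
        keep <- stats::runif(N) < 0.5            # uniform exchange
        repair(c(p1[keep], p2[!keep]))
      } else {
        p1
      }
      child <- mutate(child)
      k <- k + 1L
      newpop[[k]] <- child
    }
    pop <- newpop
    fitness <- vapply(pop, fit1, 0)
    gbest <- min(fitness)
    if (gbest < best_fit - 1e-15) {
      best_fit <- gbest
      best_subset <- pop[[which.min(fitness)]]
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    trace <- rbind(trace, data.frame(generation = gen,
                                     best = min(best_fit, gbest),
                                     mean = mean(fitness)))
    if (!is.null(config$early_stop_patience) &&
        stagnant >= config$early_stop_patience) break
  }
  structure(list(best_subset = best_subset, best_fitness = best_fit,
                 fitness_trace = trace, evaluations = evals,
                 seed = config$seed),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best PRESS = %.6g at subset {%s} (%d evaluations)\n",
              x$best_fitness, paste(x$best_subset, collapse = ","),
              x$evaluations))
  invisible(x)
}

#' Exhaustive descriptor-subset search (oracle)
#'
#' Evaluates the LOO-PRESS of every size-N subset; ties broken
#' lexicographically. Guarded to `choose(p, N) <= 1e5` combinations.
#'
#' @param data an `ecga_data`.
#' @param N subset size.
#' @param p total number of descriptors (default from `data`).
#' @param ... passed to the fitness evaluations.
#' @return list with `best_subset`, `best_fitness`, `evaluations`.
#' @export
exhaustive_search <- function(data, N, p = NULL, ...) {
  if (is.null(p)) p <- length(attr(data, "descriptor_names"))
  if (choose(p, N) > 1e5) stop("combinatorial guard exceeded: choose(p, N) > 1e5")
  combos <- utils::combn(p, N)
  fits <- apply(combos, 2, function(s) {
    pt <- suppressWarnings(loo_predictions(data, as.integer(s), ...))
    press(pt$A_exp, pt$A_calc)
  })
  best <- which.min(fits)   # which.min returns the first (lexicographic) tie
  list(best_subset = as.integer(combos[, best]), best_fitness = fits[best],
       evaluations = ncol(combos))
}
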