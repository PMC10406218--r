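#' Genetic algorithm configuration
#'
#' Settings for the binary-mask genetic algorithm that maximizes the
#' rank-AUC separation of Self and MZT training pairs. The documented
#' defaults are the full-scale settings (population 2000, up to 10,000
#' generations, bottom-10% elimination, 1% per-gene mutation, stop at
#' AUC = 1); [ga_config_desk()] gives a small profile suitable for
#' interactive work and testing.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param max_generations First termination condition: stop after this many
#'   evolution steps.
#' @param elimination_fraction Fraction of each generation (lowest fitness)
#'   excluded from parenthood; `floor(fraction * population)` individuals
#'   are eliminated.
#' @param mutation_rate Per-gene flip probability in offspring.
#' @param target_fitness Second termination condition: stop as soon as the
#'   best fitness reaches this value (default 1, i.e. complete separation).
#' @param seed RNG seed for the whole run; `NULL` uses the current state.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 2000, max_generations = 10000,
                      elimination_fraction = 0.10, mutation_rate = 0.01,
                      target_fitness = 1.0, seed = NULL) {
  cfg <- list(population_size = as.integer(population_size),
              max_generations = as.integer(max_generations),
              elimination_fraction = elimination_fraction,
              mutation_rate = mutation_rate,
              target_fitness = target_fitness,
              seed = seed)
  if (cfg$population_size < 2L) stop("population_size must be >= 2")
  if (cfg$elimination_fraction < 0 || cfg$elimination_fraction >= 1)
    stop("elimination_fraction must lie in [0, 1)")
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1)
    stop("mutation_rate must lie in [0, 1]")
  if (cfg$max_generations < 0) stop("max_generations must be >= 0")
  class(cfg) <- "ga_config"
  cfg
}

#' @rdname ga_config
#' @export
ga_config_desk <- function(population_size = 200, max_generations = 500,
                           ...) {
  ga_config(population_size = population_size,
            max_generations = max_generations, ...)
}

#' Fitness of a feature mask
#'
#' Computes the masked distance for every training pair and returns the
#' rank-AUC between the Self and MZT groups. The all-zero mask has fitness
#' 0 by definition (it carries no information).
#'
#' @param mask Binary feature mask (length = number of features).
#' @param pairs Training pair data frame (one interval class; must contain
#'   both relationships).
#' @param table A [feature_table].
#' @param distance Distance kind, as in [pair_distances()].
#' @return AUC in `[0, 1]`.
#' @export
ga_fitness <- function(mask, pairs, table,
                       distance = c("jaccard", "braycurtis", "hellinger")) {
  distance <- match.arg(distance)
  is_self <- pairs$relationship == "Self"
  if (!any(is_self) || !any(!is_self))
    stop("training pairs must contain both Self and MZT pairs")
  if (sum(mask) == 0) return(0)
  d <- pair_distances(table, pairs, distance, mask)
  rank_auc(d[is_self], d[!is_self])
}

#' Parent selection with elimination
#'
#' The lowest `elimination_fraction` of the population by fitness
#' (`floor(fraction * N)` individuals, ties broken by original index order)
#' is eliminated; the survivors are sampled with replacement with
#' probability proportional to their fitness. If every survivor has zero
#' fitness, sampling is uniform over survivors.
#'
#' @param fitnesses Numeric vector of fitness values, one per individual.
#' @param n_parents Number of parent indices to draw.
#' @param elimination_fraction Fraction eliminated before sampling.
#' @return Integer vector of `n_parents` indices into `fitnesses`.
#' @export
ga_select_parents <- function(fitnesses, n_parents,
                              elimination_fraction = 0.10) {
  n <- length(fitnesses)
  n_out <- min(floor(elimination_fraction * n), n - 1L)
  ord <- order(fitnesses, seq_len(n))  # stable: ties by index
  survivors <- sort(ord[seq.int(n_out + 1L, n)])
  w <- fitnesses[survivors]
  if (sum(w) == 0) w <- rep(1, length(survivors))
  survivors[sample.int(length(survivors), n_parents, replace = TRUE,
                       prob = w)]
}

#' Uniform crossover of two masks
#'
#' Each gene is inherited from the father or the mother independently with
#' probability one half.
#'
#' @param father,mother Binary masks of equal length.
#' @return A binary mask.
#' @export
ga_crossover <- function(father, mother) {
  if (length(father) != length(mother))
    stop("parent masks differ in length")
  from_father <- stats::runif(length(father)) < 0.5
  ifelse(from_father, father, mother)
}

#' Per-gene mutation
#'
#' Flips each gene independently with probability `rate`.
#'
#' @param mask Binary mask.
#' @param rate Per-gene flip probability.
#' @return A binary mask.
#' @export
ga_mutate <- function(mask, rate) {
  flips <- stats::runif(length(mask)) < rate
  ifelse(flips, 1 - mask, mask)
}

#' Run the genetic algorithm
#'
#' Evolves a population of binary feature masks to maximize the rank-AUC
#' separation of Self and MZT training pairs. The initial population is
#' i.i.d. Bernoulli(1/2) per gene; each evolution step eliminates the
#' lowest-fitness tail, samples fathers and mothers proportionally to
#' fitness, applies uniform crossover and per-gene mutation, and evaluates
#' the offspring. The run stops when the best fitness reaches
#' `target_fitness` or after `max_generations` steps. There is no elitism
#' in the evolving population; the reported result is the best individual
#' ever evaluated. Fitness values are cached by mask, since fitness is a
#' pure function of the mask.
#'
#' @param config A [ga_config()].
#' @param pairs Training pair data frame (single interval class).
#' @param table A [feature_table].
#' @param distance Distance kind, as in [pair_distances()].
#' @return An object of class `ga_result`: list with `best_mask` (0/1
#'   integer vector named by feature), `best_fitness`, `generation_reached`
#'   (number of evolution steps executed), `trajectory` (best fitness of
#'   each evaluated population, starting with the initial one), and
#'   `terminated_by` (`"target_fitness"` or `"max_generations"`).
#' @export
run_ga <- function(config, pairs, table,
                   distance = c("jaccard", "braycurtis", "hellinger")) {
  distance <- match.arg(distance)
  stopifnot(inherits(config, "ga_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nf <- ncol(table)
  npop <- config$population_size
  is_self <- pairs$relationship == "Self"
  if (!any(is_self) || !any(!is_self))
    stop("training pairs must contain both Self and MZT pairs")

  cache <- new.env(parent = emptyenv())
  evaluate <- function(pop) {
    vapply(seq_len(nrow(pop)), function(i) {
      key <- rawToChar(as.raw(pop[i, ] + 48L))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      v <- if (sum(pop[i, ]) == 0) 0 else {
        d <- pair_distances(table, pairs, distance, pop[i, ])
        rank_auc(d[is_self], d[!is_self])
      }
      cache[[key]] <- v
      v
    }, numeric(1))
  }

  pop <- matrix(as.integer(stats::runif(npop * nf) < 0.5), nrow = npop)
  fit <- evaluate(pop)
  best_i <- which.max(fit)
  best_mask <- pop[best_i, ]
  best_fit <- fit[best_i]
  trajectory <- max(fit)
  gen <- 0L
  terminated_by <- "max_generations"
  if (best_fit >= config$target_fitness) {
    terminated_by <- "target_fitness"
  } else {
    while (gen < config$max_generations) {
      fathers <- ga_select_parents(fit, npop, config$elimination_fraction)
      mothers <- ga_select_parents(fit, npop, config$elimination_fraction)
      keep_f <- stats::runif(npop * nf) < 0.5
      muts <- stats::runif(npop * nf) < config$mutation_rate
      child <- matrix(ifelse(keep_f, pop[fathers, ], pop[mothers, ]),
                      nrow = npop)
      pop <- matrix(as.integer(ifelse(matrix(muts, nrow = npop),
                                      1L - child, child)), nrow = npop)
      fit <- evaluate(pop)
      gen <- gen + 1L
      trajectory <- c(trajectory, max(fit))
      if (max(fit) > best_fit) {
        best_i <- which.max(fit)
        best_mask <- pop[best_i, ]
        best_fit <- fit[best_i]
      }
      if (best_fit >= config$target_fitness) {
        terminated_by <- "target_fitness"
        break
      }
    }
  }
  names(best_mask) <- colnames(table)
  structure(list(best_mask = best_mask, best_fitness = best_fit,
                 generation_reached = gen, trajectory = trajectory,
                 terminated_by = terminated_by, distance = distance),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(paste0("Genetic-algorithm feature selection (%s distance)\n",
                     "  best AUC %.4f with %d of %d features selected\n",
                     "  %d generation(s); stopped by %s\n"),
              x$distance, x$best_fitness, sum(x$best_mask),
              length(x$best_mask), x$generation_reached, x$terminated_by))
  invisible(x)
}

#' Serialize a GA result to JSON
#'
#' Writes the best mask (as a 0/1 string), its fitness, the generation
#' count, termination reason and the per-generation best-AUC trajectory.
#'
#' @param result A `ga_result` from [run_ga()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ga_result <- function(result, path) {
  stopifnot(inherits(result, "ga_result"))
  json <- sprintf(
    paste0('{"best_mask": "%s", "best_fitness": %.10g, ',
           '"generation_reached": %d, "terminated_by": "%s", ',
           '"distance": "%s", "trajectory": [%s]}'),
    paste(result$best_mask, collapse = ""), result$best_fitness,
    result$generation_reached, result$terminated_by, result$distance,
    paste(sprintf("%.10g", result$trajectory), collapse = ", "))
  writeLines(json, path)
  invisible(path)
}
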