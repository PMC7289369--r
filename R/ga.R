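#' Genetic algorithm configuration
#'
#' Shared knobs of the three searches in the package (feature selection,
#' structure optimization, learning-parameter optimization): population size,
#' generation count, per-offspring crossover and mutation probabilities, the
#' RNG seed and the number of cross-validation folds used by the fitness
#' function.
#'
#' @param population_size Number of individuals (>= 2).
#' @param generations Number of generations (>= 1).
#' @param crossover_prob Probability an offspring is produced by crossover
#'   rather than copied from its first parent (default 0.9).
#' @param mutation_prob Probability an offspring is mutated (default 0.1).
#' @param seed Integer seed; the whole run is a deterministic function of it.
#' @param cv_folds Folds for cross-validated fitness (default 5).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 40L, generations = 10L,
                      crossover_prob = 0.9, mutation_prob = 0.1,
                      seed = 1L, cv_folds = 5L) {
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  cv_folds <- as.integer(cv_folds)
  if (population_size < 2L) stop("population_size must be >= 2")
  if (generations < 1L) stop("generations must be >= 1")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  if (crossover_prob < 0 || crossover_prob > 1 ||
      mutation_prob < 0 || mutation_prob > 1)
    stop("operator probabilities must lie in [0, 1]")
  structure(list(population_size = population_size,
                 generations = generations,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 seed = as.integer(seed), cv_folds = cv_folds),
            class = "ga_config")
}

#' Binary tournament selection
#'
#' Draws two individuals uniformly with replacement and returns the fitter;
#' exact fitness ties are broken uniformly at random.
#'
#' @param population List of individuals, each a list with `genome` and a
#'   numeric `fitness`.
#' @param rng A package-internal RNG stream (see `evolve`); tests may pass
#'   the value of `evobci:::local_rng(seed)`.
#' @return The selected individual.
#' @export
binary_tournament <- function(population, rng) {
  if (length(population) == 0L) stop("empty population")
  idx <- rng$sample_int(length(population), 2L, replace = TRUE)
  f1 <- population[[idx[1L]]]$fitness
  f2 <- population[[idx[2L]]]$fitness
  if (is.null(f1) || is.null(f2)) stop("tournament requires evaluated fitness")
  if (f1 > f2) return(population[[idx[1L]]])
  if (f2 > f1) return(population[[idx[2L]]])
  population[[idx[1L + (rng$runif(1) < 0.5)]]]
}

#' Elitist replacement
#'
#' Merges the current population with its offspring, ranks the union by
#' fitness (descending) and truncates to `target_size`. Ties keep insertion
#' order (current population first), making the operation deterministic.
#' Individuals whose genome is an exact copy of an already-ranked one are
#' passed over while distinct candidates remain (a duplicated genome is the
#' same solution, and fitness is cached per genome anyway); duplicates refill
#' the population only when fewer than `target_size` distinct genomes exist.
#' An offspring set identical to the population therefore leaves the
#' population unchanged.
#'
#' @param population,offspring Lists of evaluated individuals.
#' @param target_size Size of the next population.
#' @return The next population (list of individuals).
#' @export
elitist_replacement <- function(population, offspring, target_size) {
  union <- c(population, offspring)
  if (target_size > length(union))
    stop("target_size (", target_size, ") exceeds union size (",
         length(union), ")")
  fit <- vapply(union, function(ind) {
    if (is.null(ind$fitness)) stop("replacement requires evaluated fitness")
    ind$fitness
  }, numeric(1))
  ord <- order(-fit, seq_along(fit))  # stable: earlier individuals win ties
  keys <- vapply(union, function(ind) genome_key(ind$genome), character(1))
  seen <- character(0)
  firsts <- integer(0)
  dupes <- integer(0)
  for (i in ord) {
    if (keys[i] %in% seen) dupes <- c(dupes, i)
    else {
      seen <- c(seen, keys[i])
      firsts <- c(firsts, i)
    }
  }
  union[c(firsts, dupes)[seq_len(target_size)]]
}

#' Run a generational, elitist genetic algorithm
#'
#' The engine behind all three searches. Each generation produces
#' `population_size` offspring by binary-tournament parent selection,
#' crossover (with probability `crossover_prob`), mutation (with probability
#' `mutation_prob`) and an optional repair step, then merges parents and
#' offspring elitistically. Fitness values are cached per genome: a genome is
#' trained/evaluated once, and its recorded fitness never changes, so the
#' best-so-far trajectory is non-decreasing even when the underlying
#' evaluation would be stochastic. The evaluation seed of each genome is
#' derived from the run seed and the genome itself, making every cached value
#' independent of evaluation order.
#'
#' @param initial_genomes List of genomes (any encoding the operators accept).
#' @param operators List with elements `crossover = function(a, b, rng)`,
#'   `mutate = function(genome, rng)` and optionally
#'   `repair = function(genome, rng)`.
#' @param fitness_fn `function(genome, seed)` returning a fitness in `[0, 1]`
#'   (cross-validated accuracy throughout this package).
#' @param config A [ga_config()].
#' @return An object of class `ga_result`: `best_individual`,
#'   `best_fitness_per_generation` (length `generations + 1`, the first entry
#'   being the initial population's best), `mean_fitness_per_generation`,
#'   `final_population`, and `evaluations` (number of distinct genomes
#'   evaluated).
#' @export
evolve <- function(initial_genomes, operators, fitness_fn, config) {
  stopifnot(inherits(config, "ga_config"))
  if (length(initial_genomes) < 1L) stop("empty initial population")
  rng <- local_rng(config$seed)
  cache <- new.env(parent = emptyenv())
  evaluations <- 0L

  evaluate <- function(genome) {
    key <- genome_key(genome)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- fitness_fn(genome, derive_seed(config$seed, key))
    if (!is.finite(f) || f < 0 || f > 1)
      stop("fitness_fn returned ", f, "; fitness must lie in [0, 1]")
    cache[[key]] <- f
    evaluations <<- evaluations + 1L
    f
  }

  population <- lapply(initial_genomes, function(g)
    list(genome = g, fitness = evaluate(g)))

  best_series <- numeric(config$generations + 1L)
  mean_series <- numeric(config$generations + 1L)
  fits <- vapply(population, `[[`, numeric(1), "fitness")
  best_series[1L] <- max(fits)
  mean_series[1L] <- mean(fits)

  for (gen in seq_len(config$generations)) {
    offspring <- vector("list", config$population_size)
    for (i in seq_len(config$population_size)) {
      p1 <- binary_tournament(population, rng)
      child <- if (rng$runif(1) < config$crossover_prob) {
        p2 <- binary_tournament(population, rng)
        operators$crossover(p1$genome, p2$genome, rng)
      } else p1$genome
      if (rng$runif(1) < config$mutation_prob)
        child <- operators$mutate(child, rng)
      if (!is.null(operators$repair))
        child <- operators$repair(child, rng)
      offspring[[i]] <- list(genome = child, fitness = evaluate(child))
    }
    population <- elitist_replacement(population, offspring,
                                      config$population_size)
    fits <- vapply(population, `[[`, numeric(1), "fitness")
    best_series[gen + 1L] <- max(fits)
    mean_series[gen + 1L] <- mean(fits)
  }

  fits <- vapply(population, `[[`, numeric(1), "fitness")
  structure(list(best_individual = population[[which.max(fits)]],
                 best_fitness_per_generation = best_series,
                 mean_fitness_per_generation = mean_series,
                 final_population = population,
                 evaluations = evaluations,
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA run:", x$config$population_size, "individuals,",
      x$config$generations, "generations,", x$evaluations,
      "distinct genomes evaluated\n")
  cat(sprintf("Best fitness: %.4f (initial %.4f)\n",
              x$best_individual$fitness,
              x$best_fitness_per_generation[1L]))
  invisible(x)
}

#' @export
plot.ga_result <- function(x, ...) {
  gens <- seq_along(x$best_fitness_per_generation) - 1L
  graphics::plot(gens, x$best_fitness_per_generation, type = "s",
                 xlab = "generation", ylab = "CV accuracy",
                 ylim = range(c(x$best_fitness_per_generation,
                                x$mean_fitness_per_generation)), ...)
  graphics::lines(gens, x$mean_fitness_per_generation, lty = 2)
  graphics::legend("bottomright", legend = c("best", "mean"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' @param labels Integer class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per observation; folds
#'   partition the indices and each class is spread evenly across folds.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  rng <- local_rng(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    if (length(members) < k)
      stop("class ", cl, " has ", length(members),
           " members; k-fold CV with k = ", k, " requires at least ", k)
    shuffled <- rng$sample(members)
    folds[shuffled] <- rep_len(seq_len(k), length(members))
  }
  folds
}

#' Cross-validated accuracy of a classifier on a feature matrix
#'
#' Stratified k-fold cross-validation: the model factory is fitted on each
#' training portion and scored on the held-out fold; the returned fitness is
#' the arithmetic mean of the k held-out accuracies.
#'
#' @param matrix A [feature_matrix()].
#' @param model_factory `function(train_matrix, seed)` returning a prediction
#'   function `function(values) -> integer labels`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment and model training.
#' @return Mean held-out accuracy in `[0, 1]`.
#' @export
kfold_cv_fitness <- function(matrix, model_factory, k = 5L, seed = 1L) {
  stopifnot(inherits(matrix, "feature_matrix"))
  folds <- stratified_folds(matrix$labels, k, seed)
  acc <- numeric(k)
  for (fold in seq_len(k)) {
    tr_idx <- folds != fold
    train <- feature_matrix(matrix$values[tr_idx, , drop = FALSE],
                            matrix$labels[tr_idx], matrix$feature_names)
    predictor <- model_factory(train, derive_seed(seed, paste0("fold", fold)))
    pred <- predictor(matrix$values[!tr_idx, , drop = FALSE])
    acc[fold] <- mean(pred == matrix$labels[!tr_idx])
  }
  mean(acc)
}
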