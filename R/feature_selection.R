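#' Genetic wrapper feature selection over binary masks
#'
#' Candidate feature subsets are encoded as binary masks (one bit per
#' feature, 1 = active). Fitness is the cross-validated accuracy of a light
#' classifier trained on the active columns only, so the selector directly
#' optimizes downstream predictive value rather than a univariate proxy. A
#' hard cap on the number of active features (default 30) keeps subsets small
#' relative to the 3,600-dimensional pattern space; masks are repaired after
#' every variation step so the whole population stays feasible.
#'
#' @name feature_selection
NULL

as_rng <- function(rng) {
  if (is.list(rng) && !is.null(rng$sample_int)) rng else local_rng(rng)
}

#' Initialize a population of feature masks
#'
#' Each mask's active count is drawn uniformly from `1..max_active` and its
#' active positions uniformly without replacement.
#'
#' @param n Population size.
#' @param n_features Mask length (one bit per feature).
#' @param max_active Maximum number of active features per mask.
#' @param rng Integer seed or an internal RNG stream.
#' @return List of `n` integer 0/1 vectors of length `n_features`.
#' @export
init_fs_population <- function(n, n_features, max_active, rng = 1L) {
  if (max_active < 1L) stop("max_active must be >= 1")
  if (max_active > n_features) stop("max_active exceeds feature count")
  if (n < 2L) stop("population size must be >= 2")
  rng <- as_rng(rng)
  lapply(seq_len(n), function(i) {
    k <- rng$sample_int(max_active, 1L)
    mask <- integer(n_features)
    mask[rng$sample_int(n_features, k)] <- 1L
    mask
  })
}

#' Uniform crossover of two binary masks
#'
#' Bits on which the parents agree are inherited as-is; every disagreeing bit
#' is set to 0 or 1 with probability one half. All features common to both
#' parents are therefore guaranteed to be passed on.
#'
#' @param a,b Integer 0/1 vectors of equal length.
#' @param rng Integer seed or internal RNG stream.
#' @return The offspring mask.
#' @export
uniform_crossover <- function(a, b, rng = 1L) {
  if (length(a) != length(b)) stop("mask length mismatch")
  rng <- as_rng(rng)
  child <- a
  diff <- which(a != b)
  if (length(diff))
    child[diff] <- as.integer(rng$runif(length(diff)) < 0.5)
  child
}

#' Bit-flip mutation
#'
#' Inverts exactly one uniformly chosen position.
#'
#' @param mask Integer 0/1 vector.
#' @param rng Integer seed or internal RNG stream.
#' @return The mutated mask.
#' @export
bit_flip_mutation <- function(mask, rng = 1L) {
  if (length(mask) == 0L) stop("empty mask")
  rng <- as_rng(rng)
  i <- rng$sample_int(length(mask), 1L)
  mask[i] <- 1L - mask[i]
  mask
}

#' Repair a mask to the active-count constraint
#'
#' If more than `max_active` bits are set, uniformly chosen active bits are
#' cleared until the cap is met (survivors are always a subset of the
#' original active set). An all-zero mask gets one uniformly chosen bit set,
#' since an empty feature subset is untrainable.
#'
#' @param mask Integer 0/1 vector.
#' @param max_active Maximum allowed active count.
#' @param rng Integer seed or internal RNG stream.
#' @return A feasible mask with `1 <= sum(mask) <= max_active`.
#' @export
repair_constraint <- function(mask, max_active, rng = 1L) {
  if (max_active < 1L) stop("max_active must be >= 1")
  rng <- as_rng(rng)
  active <- which(mask == 1L)
  if (length(active) > max_active) {
    drop <- rng$sample(active, length(active) - max_active)
    mask[drop] <- 0L
  } else if (length(active) == 0L) {
    mask[rng$sample_int(length(mask), 1L)] <- 1L
  }
  mask
}

#' Default wrapped classifier: ridge-regularized multinomial logistic
#'
#' A light linear model so the selector can afford thousands of fitness
#' evaluations. Returns a factory compatible with [kfold_cv_fitness()].
#'
#' @param lambda Ridge penalty passed to `glmnet` (default 0.05).
#' @return `function(train_matrix, seed)` yielding a prediction function.
#' @export
logistic_factory <- function(lambda = 0.05) {
  function(train, seed) {
    x <- train$values
    # glmnet needs >= 2 predictor columns; duplicating the single column
    # leaves the fitted linear predictor unchanged up to weight sharing
    dup <- ncol(x) == 1L
    if (dup) x <- cbind(x, x)
    y <- factor(train$labels)
    if (nlevels(y) < 2L) {
      only <- train$labels[1L]
      return(function(values) rep(only, nrow(values)))
    }
    fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    function(values) {
      if (dup) values <- cbind(values, values)
      as.integer(as.character(
        stats::predict(fit, newx = values, type = "class")[, 1L]))
    }
  }
}

#' Run the genetic wrapper feature selection
#'
#' @param matrix A [feature_matrix()].
#' @param classifier_factory Factory for the wrapped model (default
#'   [logistic_factory()]).
#' @param config A [ga_config()]; the reference configuration uses a
#'   population of 1000 for 100 generations.
#' @param max_active Cap on active features per mask (default 30).
#' @return An object of class `fs_result`: `best_mask` (integer 0/1),
#'   `selected` (active feature names), `fitness` (CV accuracy of the best
#'   mask) and `ga` (the full [evolve()] result).
#' @export
run_feature_selection <- function(matrix, classifier_factory = NULL,
                                  config = ga_config(population_size = 1000L,
                                                     generations = 100L),
                                  max_active = 30L) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (is.null(classifier_factory)) classifier_factory <- logistic_factory()
  p <- ncol(matrix$values)
  init <- init_fs_population(config$population_size, p, max_active,
                             derive_seed(config$seed, "fs_init"))
  operators <- list(
    crossover = function(a, b, rng) uniform_crossover(a, b, rng),
    mutate = function(g, rng) bit_flip_mutation(g, rng),
    repair = function(g, rng) repair_constraint(g, max_active, rng)
  )
  fitness <- function(mask, seed) {
    sub <- subset_features(matrix, mask == 1L)
    kfold_cv_fitness(sub, classifier_factory, k = config$cv_folds,
                     seed = seed)
  }
  ga <- evolve(init, operators, fitness, config)
  best <- ga$best_individual$genome
  structure(list(best_mask = best,
                 selected = matrix$feature_names[best == 1L],
                 fitness = ga$best_individual$fitness,
                 ga = ga),
            class = "fs_result")
}

#' @export
print.fs_result <- function(x, ...) {
  cat("GA wrapper feature selection\n")
  cat("Selected", sum(x$best_mask), "of", length(x$best_mask),
      "features; CV accuracy", sprintf("%.4f", x$fitness), "\n")
  invisible(x)
}

#' Write selected feature identifiers, one per line
#'
#' @param x An `fs_result`.
#' @param path Output file.
#' @export
write_selected_features <- function(x, path) {
  stopifnot(inherits(x, "fs_result"))
  writeLines(x$selected, path)
  invisible(path)
}
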