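#' Two-step evolutionary hyperparameter optimization
#'
#' Hyperparameter search is split into two sequential GA runs to shrink the
#' joint search space: step 1 evolves the network structure (filter count and
#' size for the CNN, hidden widths for the FFNN, GRU units for the RNN) while
#' training every candidate with fixed baseline learning parameters (60
#' epochs, learning rate 0.1); step 2 freezes the best structure found and
#' evolves the learning parameters (learning rate, epochs, and for the FFNN
#' the dropout rate). Both steps share the GA engine: binary tournament
#' selection, elitist replacement, 5-fold cross-validated accuracy as
#' fitness.
#'
#' @name hyperopt
NULL

# per-gene bounds: lo, hi, integer?, odd?
structure_bounds <- function(family, n_inputs) {
  switch(family,
    cnn = list(
      n_filters = list(lo = 1, hi = 250, integer = TRUE, odd = FALSE),
      filter_size = list(lo = 1, hi = min(19, n_inputs), integer = TRUE,
                         odd = TRUE)),
    ffnn = list(
      width = list(lo = 1, hi = Inf, integer = TRUE, odd = FALSE)),
    rnn = list(
      gru_units = list(lo = 1, hi = 60, integer = TRUE, odd = FALSE)),
    stop("unknown family: ", family)
  )
}

clamp_gene <- function(x, b) {
  x <- min(max(x, b$lo), b$hi)
  if (isTRUE(b$integer)) x <- round(x)
  if (isTRUE(b$odd) && x %% 2 == 0)
    x <- if (x + 1 <= b$hi) x + 1 else x - 1
  max(x, b$lo)
}

#' Initialize a structure population
#'
#' Genes are sampled from a normal distribution centered at the middle of the
#' allowed range with SD = range/6 (so three standard deviations span the
#' range), clamped to the bounds; integer genes are rounded and filter sizes
#' forced odd. FFNN widths have no upper bound, so their initialization uses
#' a cap of `init_cap` (the search itself remains uncapped); FFNN depth is
#' drawn uniformly from \{1, 2\}.
#'
#' @param family `"cnn"`, `"ffnn"` or `"rnn"`.
#' @param n Population size.
#' @param n_inputs Input feature count (bounds the CNN filter size).
#' @param rng Integer seed or internal RNG stream.
#' @param init_cap Initialization range cap for unbounded FFNN widths
#'   (default 200).
#' @return List of `n` numeric genomes.
#' @export
init_structure_population <- function(family, n, n_inputs, rng = 1L,
                                      init_cap = 200) {
  rng <- as_rng(rng)
  bounds <- structure_bounds(family, n_inputs)
  draw <- function(b) {
    hi <- if (is.finite(b$hi)) b$hi else init_cap
    mid <- (b$lo + hi) / 2
    clamp_gene(rng$rnorm(1L, mid, (hi - b$lo) / 6), b)
  }
  lapply(seq_len(n), function(i) {
    if (family == "ffnn") {
      depth <- rng$sample_int(2L, 1L)
      vapply(seq_len(depth), function(j) draw(bounds$width), numeric(1))
    } else {
      vapply(bounds, draw, numeric(1))
    }
  })
}

#' Single-point crossover for fixed-length real genomes
#'
#' A cut index is drawn uniformly in `1..len-1`; the child takes genes before
#' the cut from the first parent and the rest from the second. Length-one
#' genomes (the RNN's single structural gene) degenerate to copying one
#' parent chosen uniformly.
#'
#' @param a,b Numeric genomes of equal length.
#' @param rng Integer seed or internal RNG stream.
#' @return The offspring genome.
#' @export
single_point_crossover <- function(a, b, rng = 1L) {
  if (length(a) != length(b)) stop("genome length mismatch")
  rng <- as_rng(rng)
  if (length(a) == 1L)
    return(if (rng$runif(1) < 0.5) a else b)
  cut <- rng$sample_int(length(a) - 1L, 1L)
  c(a[seq_len(cut)], b[(cut + 1L):length(b)])
}

#' Multiplicative Gaussian mutation
#'
#' One uniformly chosen gene is multiplied by a draw from `Normal(1, sigma)`,
#' then clamped/rounded back into its bounds (filter sizes are re-forced
#' odd).
#'
#' @param genes Numeric genome.
#' @param sigma Mutation SD (default 0.1).
#' @param bounds Per-gene bounds list (as from `structure_bounds`), recycled
#'   if a single bound is given.
#' @param rng Integer seed or internal RNG stream.
#' @return The mutated genome.
#' @export
gaussian_mutation <- function(genes, sigma = 0.1, bounds, rng = 1L) {
  if (sigma <= 0) stop("sigma must be > 0")
  rng <- as_rng(rng)
  i <- rng$sample_int(length(genes), 1L)
  b <- if (!is.null(bounds$lo)) bounds else
    bounds[[min(i, length(bounds))]]
  genes[i] <- clamp_gene(genes[i] * rng$rnorm(1L, 1, sigma), b)
  genes
}

#' Midpoint crossover for variable-depth FFNN structures
#'
#' The child inherits the first `ceiling(len(a)/2)` widths from one parent
#' and the last `ceiling(len(b)/2)` widths from the other, truncated to the
#' maximum depth of two hidden layers.
#'
#' @param a,b Numeric FFNN width genomes (length 1 or 2).
#' @param rng Integer seed or internal RNG stream (unused; kept for operator
#'   interface symmetry).
#' @return The offspring genome.
#' @export
midpoint_crossover <- function(a, b, rng = 1L) {
  ha <- a[seq_len(ceiling(length(a) / 2))]
  hb <- b[(length(b) - ceiling(length(b) / 2) + 1L):length(b)]
  utils::head(c(ha, hb), 2L)
}

#' Single-layer / scaling mutation for FFNN structures
#'
#' With probability one half a single uniformly chosen width is multiplied by
#' a `Normal(1, sigma)` draw (single-layer mutation); otherwise all widths
#' are multiplied by one shared draw (scaling mutation, preserving the layer
#' ratio up to rounding). Widths are rounded with a floor of 1.
#'
#' @param genes Numeric width genome.
#' @param sigma Mutation SD (default 0.1).
#' @param rng Integer seed or internal RNG stream.
#' @return The mutated genome.
#' @export
ffnn_mutation <- function(genes, sigma = 0.1, rng = 1L) {
  rng <- as_rng(rng)
  if (rng$runif(1) < 0.5) {
    i <- rng$sample_int(length(genes), 1L)
    genes[i] <- genes[i] * rng$rnorm(1L, 1, sigma)
  } else {
    genes <- genes * rng$rnorm(1L, 1, sigma)
  }
  pmax(round(genes), 1)
}

#' Decode a structure genome into a network specification
#'
#' @param family `"cnn"`, `"ffnn"` or `"rnn"`.
#' @param genes Numeric structure genome.
#' @param n_inputs,n_classes Data dimensions.
#' @param dropout_rate FFNN dropout (a learning-step parameter; default 0).
#' @return A network spec (see [cnn_spec()]).
#' @export
decode_structure <- function(family, genes, n_inputs, n_classes,
                             dropout_rate = 0) {
  switch(family,
    cnn = cnn_spec(genes[1L], genes[2L], n_inputs, n_classes),
    ffnn = ffnn_spec(genes, n_inputs, n_classes,
                     dropout_rate = dropout_rate),
    rnn = rnn_spec(genes[1L], n_inputs, n_classes))
}

learning_bounds <- function(family) {
  b <- list(learning_rate = list(lo = 1e-4, hi = 1, integer = FALSE,
                                 odd = FALSE),
            epochs = list(lo = 1, hi = 200, integer = TRUE, odd = FALSE))
  if (family == "ffnn")
    b$dropout_rate <- list(lo = 0, hi = 0.9, integer = FALSE, odd = FALSE)
  b
}

#' Decode a learning genome into training parameters
#'
#' @param family Network family.
#' @param genes `(learning_rate, epochs)` plus `dropout_rate` for the FFNN.
#' @param batch_size,seed Passed through to [training_params()].
#' @return A [training_params()].
#' @export
decode_learning <- function(family, genes, batch_size = 16L, seed = 1L) {
  training_params(learning_rate = genes[1L], epochs = genes[2L],
                  dropout_rate = if (family == "ffnn") genes[3L] else 0,
                  batch_size = batch_size, seed = seed)
}

net_factory <- function(spec_fn, tparams) {
  function(train, seed) {
    tp <- tparams
    tp$seed <- seed
    model <- train_model(build_model(spec_fn(train)), train, tp)
    function(values) predict(model, values)
  }
}

# Candidates whose training diverges (non-finite loss, typically from an
# aggressive learning rate) are worthless models, not errors of the search:
# they receive fitness 0 and selection weeds them out.
safe_cv_fitness <- function(matrix, factory, k, seed) {
  tryCatch(kfold_cv_fitness(matrix, factory, k = k, seed = seed),
           error = function(e) {
             if (grepl("non-finite training loss", conditionMessage(e)))
               return(0)
             stop(e)
           })
}

#' Step 1: evolve the network structure
#'
#' Fitness of a candidate structure is its 5-fold cross-validated accuracy
#' when trained with fixed baseline learning parameters (default 60 epochs,
#' learning rate 0.1).
#'
#' @param family `"cnn"`, `"ffnn"` or `"rnn"`.
#' @param matrix A [feature_matrix()] (already restricted to the selected
#'   features where feature selection is used).
#' @param config A [ga_config()] (reference setting: 40 individuals, 10
#'   generations).
#' @param step1_params Baseline [training_params()] used to train every
#'   candidate.
#' @param sigma Multiplicative mutation SD (default 0.1).
#' @param incumbent Optional structure genome seeded into the initial
#'   population (e.g. a hand-tuned reference structure). With elitist
#'   replacement the search then never returns a structure with lower CV
#'   fitness than the incumbent, making "optimization improves on the
#'   default" hold by construction at the fitness level.
#' @return List with `best_genes`, `best_spec` and `ga` (a `ga_result`).
#' @export
optimize_structure <- function(family, matrix,
                               config = ga_config(),
                               step1_params = training_params(
                                 learning_rate = 0.1, epochs = 60L),
                               sigma = 0.1, incumbent = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  n_inputs <- ncol(matrix$values)
  n_classes <- length(unique(matrix$labels))
  bounds <- structure_bounds(family, n_inputs)
  init <- init_structure_population(family, config$population_size, n_inputs,
                                    derive_seed(config$seed, "struct_init"))
  if (!is.null(incumbent)) init[[1L]] <- incumbent
  operators <- if (family == "ffnn") {
    list(crossover = function(a, b, rng) midpoint_crossover(a, b, rng),
         mutate = function(g, rng) ffnn_mutation(g, sigma, rng))
  } else {
    list(crossover = function(a, b, rng) single_point_crossover(a, b, rng),
         mutate = function(g, rng) {
           out <- gaussian_mutation(g, sigma, bounds, rng)
           vapply(seq_along(out), function(i)
             clamp_gene(out[i], bounds[[i]]), numeric(1))
         })
  }
  fitness <- function(genes, seed) {
    factory <- net_factory(function(train)
      decode_structure(family, genes, ncol(train$values), n_classes),
      step1_params)
    safe_cv_fitness(matrix, factory, config$cv_folds, seed)
  }
  ga <- evolve(init, operators, fitness, config)
  best <- ga$best_individual$genome
  list(best_genes = best,
       best_spec = decode_structure(family, best, n_inputs, n_classes),
       ga = ga)
}

#' Step 2: evolve the learning parameters for a fixed structure
#'
#' Genes are `(learning_rate, epochs)` plus `dropout_rate` for the FFNN;
#' single-point crossover and multiplicative Gaussian mutation as in step 1.
#' For the FFNN, mutation chooses uniformly between the generic Gaussian
#' mutation (learning rate or epochs) and a dropout-specific Gaussian.
#' The structure genes are never altered in this step.
#'
#' @param family Network family.
#' @param structure_genes Structure genome from [optimize_structure()].
#' @param matrix A [feature_matrix()].
#' @param config A [ga_config()].
#' @param sigma Mutation SD (default 0.1).
#' @param batch_size Minibatch size used when training candidates.
#' @param incumbent [training_params()] whose genes seed one member of the
#'   initial population — by default the step-1 baseline (learning rate 0.1,
#'   60 epochs). With elitist replacement this guarantees the second step
#'   never returns a configuration with lower CV fitness than the structure
#'   step's own training setting.
#' @return List with `best_genes`, `best_params` (a [training_params()]) and
#'   `ga`.
#' @export
optimize_learning <- function(family, structure_genes, matrix,
                              config = ga_config(), sigma = 0.1,
                              batch_size = 16L,
                              incumbent = training_params(
                                learning_rate = 0.1, epochs = 60L)) {
  stopifnot(inherits(matrix, "feature_matrix"))
  n_classes <- length(unique(matrix$labels))
  bounds <- learning_bounds(family)
  rng0 <- local_rng(derive_seed(config$seed, "learn_init"))
  draw <- function(b) {
    mid <- (b$lo + b$hi) / 2
    clamp_gene(rng0$rnorm(1L, mid, (b$hi - b$lo) / 6), b)
  }
  init <- lapply(seq_len(config$population_size), function(i)
    vapply(bounds, draw, numeric(1)))
  if (!is.null(incumbent)) {
    inc <- c(incumbent$learning_rate, incumbent$epochs)
    if (family == "ffnn") inc <- c(inc, incumbent$dropout_rate)
    init[[1L]] <- vapply(seq_along(bounds), function(i)
      clamp_gene(inc[i], bounds[[i]]), numeric(1))
  }
  mutate <- function(g, rng) {
    if (family == "ffnn" && rng$runif(1) < 0.5) {
      g[3L] <- clamp_gene(g[3L] * rng$rnorm(1L, 1, sigma),
                          bounds$dropout_rate)
      # a dropout of exactly 0 cannot escape multiplicatively; nudge instead
      if (g[3L] == 0) g[3L] <- clamp_gene(abs(rng$rnorm(1L, 0, sigma)),
                                          bounds$dropout_rate)
      g
    } else {
      i <- rng$sample_int(2L, 1L)
      g[i] <- clamp_gene(g[i] * rng$rnorm(1L, 1, sigma), bounds[[i]])
      g
    }
  }
  fitness <- function(genes, seed) {
    tp <- decode_learning(family, genes, batch_size = batch_size)
    factory <- net_factory(function(train)
      decode_structure(family, structure_genes, ncol(train$values),
                       n_classes,
                       dropout_rate = tp$dropout_rate), tp)
    safe_cv_fitness(matrix, factory, config$cv_folds, seed)
  }
  operators <- list(
    crossover = function(a, b, rng) single_point_crossover(a, b, rng),
    mutate = mutate)
  ga <- evolve(init, operators, fitness, config)
  best <- ga$best_individual$genome
  list(best_genes = best,
       best_params = decode_learning(family, best, batch_size = batch_size),
       ga = ga)
}

#' Run the full two-step optimization
#'
#' [optimize_structure()] followed by [optimize_learning()] with the best
#' structure of step 1; returns a complete, re-creatable model specification.
#'
#' @param family `"cnn"`, `"ffnn"` or `"rnn"`.
#' @param matrix A [feature_matrix()].
#' @param structure_config,learning_config [ga_config()]s for the two steps
#'   (reference setting: 40 individuals, 10 generations each).
#' @param step1_params Baseline training parameters for step-1 fitness.
#' @param sigma Mutation SD for both steps.
#' @param incumbent_structure Optional structure genome passed to
#'   [optimize_structure()] as a warm start.
#' @return An object of class `model_spec`: `family`, `structure_genes`,
#'   `training` (a [training_params()]), `seed`, plus both `ga_result`s
#'   (`structure_ga`, `learning_ga`) and the step fitness values.
#' @export
two_step_optimize <- function(family, matrix,
                              structure_config = ga_config(),
                              learning_config = structure_config,
                              step1_params = training_params(
                                learning_rate = 0.1, epochs = 60L),
                              sigma = 0.1, incumbent_structure = NULL) {
  step1 <- optimize_structure(family, matrix, structure_config,
                              step1_params, sigma, incumbent_structure)
  step2 <- optimize_learning(family, step1$best_genes, matrix,
                             learning_config, sigma,
                             incumbent = step1_params)
  structure(list(family = family,
                 structure_genes = step1$best_genes,
                 learning_genes = step2$best_genes,
                 training = step2$best_params,
                 seed = structure_config$seed,
                 structure_fitness = step1$ga$best_individual$fitness,
                 learning_fitness = step2$ga$best_individual$fitness,
                 structure_ga = step1$ga,
                 learning_ga = step2$ga),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Optimized model spec (", x$family, ")\n", sep = "")
  cat("Structure genes:", paste(round(x$structure_genes, 3),
                                collapse = ", "), "\n")
  cat(sprintf(
    "Training: lr %.4g, %d epochs, dropout %.3g\n",
    x$training$learning_rate, x$training$epochs, x$training$dropout_rate))
  cat(sprintf("CV fitness: structure step %.4f, learning step %.4f\n",
              x$structure_fitness, x$learning_fitness))
  invisible(x)
}

#' Serialize / restore a model specification
#'
#' Structured-text (YAML) round trip of everything needed to re-create the
#' model: family, structure and learning genes, training parameters and seed.
#'
#' @param x A `model_spec`.
#' @param path File path.
#' @export
write_model_spec <- function(x, path) {
  stopifnot(inherits(x, "model_spec"))
  yaml::write_yaml(list(
    family = x$family,
    structure_genes = as.numeric(x$structure_genes),
    learning_genes = as.numeric(x$learning_genes),
    training = list(learning_rate = x$training$learning_rate,
                    epochs = x$training$epochs,
                    dropout_rate = x$training$dropout_rate,
                    batch_size = x$training$batch_size),
    seed = x$seed), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @return `read_model_spec` returns a `model_spec` (without the GA traces).
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  tp <- training_params(learning_rate = y$training$learning_rate,
                        epochs = y$training$epochs,
                        dropout_rate = y$training$dropout_rate,
                        batch_size = y$training$batch_size)
  structure(list(family = y$family,
                 structure_genes = as.numeric(y$structure_genes),
                 learning_genes = as.numeric(y$learning_genes),
                 training = tp, seed = y$seed,
                 structure_fitness = NA_real_, learning_fitness = NA_real_,
                 structure_ga = NULL, learning_ga = NULL),
            class = "model_spec")
}
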