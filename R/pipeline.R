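#' End-to-end experiment configuration
#'
#' One structured-text-serializable object holding the knobs of every stage.
#' A single global seed fans out deterministically to per-stage seeds (by
#' stage-name hashing), so any stage can be reproduced in isolation. Unknown
#' keys in a config file are rejected.
#'
#' @param families Character vector of network families to optimize.
#' @param use_fs Named logical: whether to run feature selection per family.
#'   Defaults to the study's choices: no FS for the CNN (its convolution does
#'   implicit feature weighting and external FS was found harmful), FS for
#'   FFNN and RNN.
#' @param input Either `list(type = "patterns", n_patterns, n_features,
#'   n_informative, effect_size, n_classes)` for direct feature fixtures, or
#'   `list(type = "trials", sim = simulation_config(...), mra =
#'   mra_config(...))` for raw-signal simulation plus wavelet-variance
#'   extraction.
#' @param fs_pop,fs_gens,max_active Feature-selection GA size and constraint.
#' @param opt_pop,opt_gens GA size for each optimization step.
#' @param n_repetitions Final repeated train/evaluate runs per family.
#' @param train_fraction Stratified train share (default 0.7).
#' @param rope Rope bounds for the Bayesian comparisons.
#' @param seed Global seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(families = c("cnn", "ffnn", "rnn"),
                       use_fs = c(cnn = FALSE, ffnn = TRUE, rnn = TRUE),
                       input = list(type = "patterns", n_patterns = 178L,
                                    n_features = 200L, n_informative = 10L,
                                    effect_size = 1, n_classes = 3L),
                       fs_pop = 100L, fs_gens = 30L, max_active = 30L,
                       opt_pop = 40L, opt_gens = 10L,
                       n_repetitions = 15L, train_fraction = 0.7,
                       rope = c(-0.01, 0.01), seed = 1L) {
  families <- match.arg(families, c("cnn", "ffnn", "rnn"),
                        several.ok = TRUE)
  structure(list(families = families, use_fs = use_fs, input = input,
                 fs_pop = as.integer(fs_pop), fs_gens = as.integer(fs_gens),
                 max_active = as.integer(max_active),
                 opt_pop = as.integer(opt_pop),
                 opt_gens = as.integer(opt_gens),
                 n_repetitions = as.integer(n_repetitions),
                 train_fraction = train_fraction, rope = rope,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / restore a run configuration (YAML)
#'
#' @param config A [run_config()].
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  obj$use_fs <- as.list(obj$use_fs)  # keep names through the YAML map
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  y$use_fs <- unlist(y$use_fs)
  do.call(run_config, y)
}

#' Run the full experiment pipeline
#'
#' Data preparation (simulation or pattern generation, stratified 70/30
#' split, train-fitted normalization for raw-trial inputs), optional GA
#' feature selection per family, the two-step hyperparameter optimization,
#' repeated train/evaluate runs of each optimized model, and — when at least
#' two families are requested — the statistical comparison of their per-run
#' Kappa series.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory: stage outputs (selected features, model
#'   specs, per-family results table, comparison report) are written as
#'   plain text, each alongside the seed that produced it.
#' @param matrix Optional pre-built [feature_matrix()] overriding
#'   `config$input`.
#' @return An object of class `pipeline_report`: per-family `fs`, `spec` and
#'   `runs`, the `comparison` (or `NULL`), and a config echo.
#' @export
run_pipeline <- function(config, out_dir = NULL, matrix = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(matrix)) {
    inp <- config$input
    if (identical(inp$type, "trials")) {
      sim <- inp$sim %||% simulation_config(seed = derive_seed(config$seed,
                                                               "simulate"))
      trials <- generate_mi_trials(sim)
      matrix <- extract_features(trials, inp$mra %||% mra_config())
    } else {
      matrix <- generate_feature_patterns(
        inp$n_patterns %||% 178L, inp$n_features %||% 200L,
        inp$n_informative %||% 10L, inp$effect_size %||% 1,
        inp$n_classes %||% 3L, derive_seed(config$seed, "patterns"))$matrix
    }
  }

  split <- train_test_split(matrix, config$train_fraction,
                            derive_seed(config$seed, "split"))
  norm <- normalize_features(split$train, split$test)
  train <- norm$train
  test <- norm$others[[1L]]

  families <- config$families
  results <- list()
  for (family in families) {
    fam_train <- train
    fam_test <- test
    fs <- NULL
    if (isTRUE(config$use_fs[[family]])) {
      fs <- run_feature_selection(
        train,
        config = ga_config(config$fs_pop, config$fs_gens,
                           seed = derive_seed(config$seed,
                                              paste0("fs_", family))),
        max_active = config$max_active)
      fam_train <- subset_features(train, fs$best_mask == 1L)
      fam_test <- subset_features(test, fs$best_mask == 1L)
      if (!is.null(out_dir))
        write_selected_features(fs, file.path(out_dir,
                                              paste0("selected_", family,
                                                     ".txt")))
    }
    spec <- two_step_optimize(
      family, fam_train,
      structure_config = ga_config(config$opt_pop, config$opt_gens,
                                   seed = derive_seed(config$seed,
                                                      paste0("struct_",
                                                             family))),
      learning_config = ga_config(config$opt_pop, config$opt_gens,
                                  seed = derive_seed(config$seed,
                                                     paste0("learn_",
                                                            family))))
    runs <- repeated_runs(spec, fam_train, fam_test, config$n_repetitions,
                          base_seed = derive_seed(config$seed,
                                                  paste0("runs_", family)))
    if (!is.null(out_dir))
      write_model_spec(spec, file.path(out_dir,
                                       paste0("modelspec_", family,
                                              ".yaml")))
    results[[family]] <- list(fs = fs, spec = spec, runs = runs)
  }

  comparison <- NULL
  if (length(families) >= 2L) {
    kmat <- vapply(results, function(r) r$runs$per_run_kappa,
                   numeric(config$n_repetitions))
    colnames(kmat) <- families
    comparison <- compare_methods(kmat, config$rope[1L], config$rope[2L],
                                  seed = derive_seed(config$seed, "compare"))
  }

  report <- structure(list(results = results, comparison = comparison,
                           config = config),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    tab <- data.frame(
      family = families,
      mean_kappa = vapply(results, function(r) r$runs$mean, numeric(1)),
      sd_kappa = vapply(results, function(r) r$runs$sd, numeric(1)),
      best_kappa = vapply(results, function(r) r$runs$best, numeric(1)),
      seed = config$seed)
    utils::write.table(tab, file.path(out_dir, "results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_run_config(config, file.path(out_dir, "config_echo.yaml"))
    if (!is.null(comparison))
      write_comparison_report(comparison, file.path(out_dir, "comparison"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$config$seed, ")\n")
  for (family in names(x$results)) {
    r <- x$results[[family]]
    cat(sprintf("  %-5s kappa %.4f +/- %.4f (best %.4f)%s\n", family,
                r$runs$mean, r$runs$sd, r$runs$best,
                if (!is.null(r$fs))
                  sprintf("  [%d features selected]", sum(r$fs$best_mask))
                else ""))
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
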