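#' Cohen's Kappa from a confusion matrix
#'
#' Chance-corrected agreement `kappa = (p0 - pc) / (1 - pc)`, where `p0` is
#' the observed accuracy (trace over total) and `pc` the chance agreement,
#' i.e. the sum over classes of the products of the row and column marginal
#' proportions.
#'
#' @param confusion Square numeric matrix of counts, rows = true class,
#'   columns = predicted class.
#' @return A number in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix not square")
  total <- sum(confusion)
  if (total <= 0) stop("empty confusion matrix")
  p0 <- sum(diag(confusion)) / total
  pc <- sum((rowSums(confusion) / total) * (colSums(confusion) / total))
  if (pc >= 1)
    stop("degenerate confusion matrix: chance agreement is 1")
  (p0 - pc) / (1 - pc)
}

#' Confusion matrix of integer label vectors
#'
#' @param truth,predicted Integer labels in `0..n_classes-1`.
#' @param n_classes Number of classes (defaults to the labels present).
#' @return `n_classes x n_classes` count matrix, rows = true class.
#' @export
confusion_matrix <- function(truth, predicted, n_classes = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ")
  if (is.null(n_classes)) n_classes <- max(c(truth, predicted)) + 1L
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1L),
                              pred = 0:(n_classes - 1L)))
  for (i in seq_along(truth))
    m[truth[i] + 1L, predicted[i] + 1L] <- m[truth[i] + 1L,
                                             predicted[i] + 1L] + 1L
  m
}

#' Evaluate a trained model on a test set
#'
#' @param model A trained `mi_network`.
#' @param test A [feature_matrix()].
#' @return An object of class `eval_result` with the confusion matrix,
#'   accuracy `p0`, chance agreement `p_c` and `kappa`.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(test, "feature_matrix"))
  pred <- predict(model, test$values)
  n_classes <- max(model$spec$n_classes, max(test$labels) + 1L)
  confusion <- confusion_matrix(test$labels, pred, n_classes)
  total <- sum(confusion)
  p0 <- sum(diag(confusion)) / total
  pc <- sum((rowSums(confusion) / total) * (colSums(confusion) / total))
  structure(list(confusion = confusion, p0 = p0, p_c = pc,
                 kappa = cohen_kappa(confusion)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Accuracy %.4f, chance agreement %.4f, kappa %.4f\n",
              x$p0, x$p_c, x$kappa))
  print(x$confusion)
  invisible(x)
}

#' A plain (non-optimized) model specification
#'
#' Wraps a fixed structure and fixed training parameters in the same
#' `model_spec` shape that [two_step_optimize()] returns, so baselines and
#' optimized models run through the same evaluation code.
#'
#' @param family `"cnn"`, `"ffnn"` or `"rnn"`.
#' @param structure_genes Numeric structure genome (see
#'   [decode_structure()]).
#' @param training A [training_params()].
#' @return A `model_spec`.
#' @export
baseline_spec <- function(family, structure_genes,
                          training = training_params(learning_rate = 0.1,
                                                     epochs = 60L)) {
  structure(list(family = family,
                 structure_genes = structure_genes,
                 learning_genes = c(training$learning_rate, training$epochs,
                                    training$dropout_rate),
                 training = training, seed = training$seed,
                 structure_fitness = NA_real_, learning_fitness = NA_real_,
                 structure_ga = NULL, learning_ga = NULL),
            class = "model_spec")
}

#' Repeated train/evaluate runs of a model specification
#'
#' Trains the specified model `n_repetitions` times with consecutive seeds
#' (`base_seed .. base_seed + n - 1`), evaluates each run on the held-out
#' test set, and summarizes the per-run Kappa values as mean, standard
#' deviation and best — the format used to report repeated executions.
#'
#' @param spec A `model_spec` (from [two_step_optimize()] or
#'   [baseline_spec()]).
#' @param train,test [feature_matrix()] objects.
#' @param n_repetitions Number of runs (default 15).
#' @param base_seed First training seed.
#' @return An object of class `run_summary`: `per_run_kappa`, `mean`, `sd`,
#'   `best`, plus the per-run accuracies.
#' @export
repeated_runs <- function(spec, train, test, n_repetitions = 15L,
                          base_seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), n_repetitions >= 1L)
  n_classes <- length(unique(c(train$labels, test$labels)))
  kappas <- numeric(n_repetitions)
  accs <- numeric(n_repetitions)
  for (i in seq_len(n_repetitions)) {
    tp <- spec$training
    tp$seed <- as.integer(base_seed) + i - 1L
    net_spec <- decode_structure(spec$family, spec$structure_genes,
                                 ncol(train$values), n_classes,
                                 dropout_rate = tp$dropout_rate)
    model <- train_model(build_model(net_spec), train, tp)
    ev <- evaluate_model(model, test)
    kappas[i] <- ev$kappa
    accs[i] <- ev$p0
  }
  structure(list(per_run_kappa = kappas, per_run_accuracy = accs,
                 mean = mean(kappas),
                 sd = if (n_repetitions > 1L) stats::sd(kappas) else 0,
                 best = max(kappas), n = n_repetitions),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("Kappa over %d runs: %.4f +/- %.4f (best %.4f)\n",
              x$n, x$mean, x$sd, x$best))
  invisible(x)
}
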