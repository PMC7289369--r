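#' Construct a feature matrix of EEG patterns
#'
#' Bundles a numeric patterns-by-features matrix with integer class labels
#' (0-based) and feature names. This is the unit every search in the package
#' consumes: the feature selector, the hyperparameter searches and the final
#' evaluation all operate on a `feature_matrix`.
#'
#' @param values Numeric matrix, patterns in rows, features in columns. No
#'   missing values are allowed.
#' @param labels Integer vector of class labels in `0..C-1`, one per row.
#' @param feature_names Optional character vector of column identifiers;
#'   defaults to the column names of `values` or `f1..fp`.
#' @return An object of class `feature_matrix` with elements `values`,
#'   `labels` and `feature_names`.
#' @export
feature_matrix <- function(values, labels, feature_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature matrix contains missing or non-finite values")
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("label count (", length(labels), ") does not match pattern count (",
         nrow(values), ")")
  if (any(labels < 0L)) stop("labels must be non-negative integers (0-based)")
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names))
      feature_names <- paste0("f", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values))
    stop("feature_names length does not match feature count")
  colnames(values) <- feature_names
  structure(list(values = values, labels = labels,
                 feature_names = as.character(feature_names)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$values), "patterns x", ncol(x$values),
      "features\n")
  tab <- table(x$labels)
  cat("Classes:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                        collapse = ", "), "\n")
  rng <- range(x$values)
  cat(sprintf("Value range: [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset the feature columns of a feature matrix
#'
#' @param x A `feature_matrix`.
#' @param mask Logical or integer column selector (e.g. an active-feature mask).
#' @return A new `feature_matrix` restricted to the selected columns.
#' @export
subset_features <- function(x, mask) {
  stopifnot(inherits(x, "feature_matrix"))
  feature_matrix(x$values[, mask, drop = FALSE], x$labels,
                 x$feature_names[mask])
}

#' Min-max normalization fitted on a training set
#'
#' Per-feature linear rescaling so that the training matrix spans exactly
#' `[0, 1]` in every non-constant column. The fitted ranges are applied to any
#' further matrices (validation/test), with values clipped into `[0, 1]` so a
#' shifted test distribution cannot escape the unit interval. Constant
#' training columns map to 0 everywhere. Fitting on the training split only
#' avoids information leaking from test patterns into the scaling.
#'
#' @param train A `feature_matrix` used to fit the ranges.
#' @param ... Further `feature_matrix` objects to transform with the ranges
#'   fitted on `train`.
#' @return A list with `train` (normalized), `others` (list of the transformed
#'   extra matrices, in input order) and `ranges` (list with per-feature `min`
#'   and `max`).
#' @export
normalize_features <- function(train, ...) {
  stopifnot(inherits(train, "feature_matrix"))
  if (nrow(train$values) == 0L) stop("training matrix is empty")
  others <- list(...)
  for (o in others) {
    stopifnot(inherits(o, "feature_matrix"))
    if (ncol(o$values) != ncol(train$values))
      stop("feature-count mismatch: train has ", ncol(train$values),
           " features, other matrix has ", ncol(o$values))
  }
  mins <- apply(train$values, 2L, min)
  maxs <- apply(train$values, 2L, max)
  span <- maxs - mins
  rescale <- function(m) {
    out <- sweep(m, 2L, mins, "-")
    nz <- span > 0
    out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, span[nz], "/")
    out[, !nz] <- 0
    out[out < 0] <- 0
    out[out > 1] <- 1
    out
  }
  tr <- feature_matrix(rescale(train$values), train$labels,
                       train$feature_names)
  oth <- lapply(others, function(o)
    feature_matrix(rescale(o$values), o$labels, o$feature_names))
  list(train = tr, others = oth, ranges = list(min = mins, max = maxs))
}

#' Write a feature matrix to delimited text
#'
#' Tab-separated, one header row of feature names plus a final `label`
#' column, full double precision so a write/read round trip is lossless.
#'
#' @param x A `feature_matrix`.
#' @param path Output file path.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  df <- as.data.frame(format(x$values, digits = 17, trim = TRUE,
                             scientific = TRUE),
                      stringsAsFactors = FALSE)
  names(df) <- x$feature_names
  df$label <- x$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from delimited text
#'
#' Expects the format written by [write_feature_matrix()]: a header row and a
#' final `label` column. Malformed rows, non-numeric cells and missing labels
#' raise parse errors naming the offending line.
#'
#' @param path Input file path.
#' @param check_range If `TRUE`, error when values fall outside `[0, 1]`
#'   (the normalized-pattern contract).
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path, check_range = FALSE) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("file '", path, "' has no data rows (empty or header-only)")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!"label" %in% header) stop("missing 'label' column in '", path, "'")
  lab_col <- match("label", header)
  p <- length(header) - 1L
  n <- length(lines) - 1L
  vals <- matrix(NA_real_, n, p)
  labels <- integer(n)
  for (i in seq_len(n)) {
    cells <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != length(header))
      stop("line ", i + 1L, ": expected ", length(header), " cells, found ",
           length(cells))
    num <- suppressWarnings(as.numeric(cells[-lab_col]))
    if (anyNA(num))
      stop("line ", i + 1L, ": non-numeric or missing feature value")
    vals[i, ] <- num
    lab <- suppressWarnings(as.integer(cells[lab_col]))
    if (is.na(lab)) stop("line ", i + 1L, ": non-integer label")
    labels[i] <- lab
  }
  if (check_range && (min(vals) < 0 || max(vals) > 1))
    stop("feature values outside [0, 1] in '", path, "'")
  feature_matrix(vals, labels, header[-lab_col])
}

#' Stratified train/test split
#'
#' Splits patterns class-by-class so label proportions are preserved. Used to
#' carve the held-out test set for the synthetic experiments (70/30 default).
#'
#' @param x A `feature_matrix`.
#' @param train_fraction Fraction of each class assigned to the training set.
#' @param seed Integer RNG seed.
#' @return List with `train` and `test` feature matrices and the `train_idx`.
#' @export
train_test_split <- function(x, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(x, "feature_matrix"),
            train_fraction > 0, train_fraction < 1)
  rng <- local_rng(seed)
  idx <- integer(0)
  for (cl in sort(unique(x$labels))) {
    members <- which(x$labels == cl)
    k <- max(1L, round(length(members) * train_fraction))
    idx <- c(idx, rng$sample(members, k))
  }
  idx <- sort(idx)
  list(
    train = feature_matrix(x$values[idx, , drop = FALSE], x$labels[idx],
                           x$feature_names),
    test = feature_matrix(x$values[-idx, , drop = FALSE], x$labels[-idx],
                          x$feature_names),
    train_idx = idx
  )
}
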