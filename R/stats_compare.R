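#' Statistical comparison of classifiers
#'
#' Frequentist and Bayesian machinery for comparing algorithms over repeated
#' observations (run-by-dataset Kappa values): the Friedman omnibus test on
#' within-observation ranks, pairwise Wilcoxon signed-rank post-hocs with
#' Holm family-wise correction, and a count-based Bayesian signed-rank test
#' whose Dirichlet posterior over (left, rope, right) is sampled and mapped
#' to barycentric coordinates for heatmap plotting.
#'
#' @name stats_compare
NULL

#' Friedman rank test with tie correction
#'
#' Values are ranked within each observation (average ranks on ties). The
#' statistic is `(k-1) * sum_j (R_j - n(k+1)/2)^2 / (A - C)` where `R_j` are
#' rank sums, `A` the sum of squared ranks and `C = n k (k+1)^2 / 4`; this
#' reduces to the classic chi-square form without ties and shrinks properly
#' in their presence. A matrix whose rows are each fully tied yields
#' statistic 0 and p = 1 rather than an error.
#'
#' @param values Numeric matrix, observations x algorithms (k >= 2 columns,
#'   n >= 2 rows).
#' @return List with `statistic` (chi-square), `df` (`k - 1`) and `p_value`.
#' @export
friedman_test <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (k < 2L || n < 2L) stop("need >= 2 algorithms and >= 2 observations")
  ranks <- t(apply(values, 1L, rank))
  Rj <- colSums(ranks)
  A <- sum(ranks^2)
  C <- n * k * (k + 1)^2 / 4
  if (A - C <= 0)  # every row completely tied
    return(list(statistic = 0, df = k - 1L, p_value = 1))
  stat <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, k - 1L, lower.tail = FALSE))
}

# exact null distribution of the signed-rank sum via convolution over the
# (possibly tied, half-integer) ranks scaled by two to stay integral
signed_rank_exact_p <- function(ranks2, w2) {
  total <- sum(ranks2)
  dist <- numeric(total + 1L)  # dist[s+1] = #assignments with scaled sum s
  dist[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(length(dist) - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  p_le <- sum(dist[seq_len(w2 + 1L)])
  p_ge <- sum(dist[(w2 + 1L):length(dist)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Paired test on `b - a`. Zero differences are dropped (the classic
#' convention), tied absolute differences receive average ranks. For 25 or
#' fewer remaining pairs the p-value comes from the exact permutation
#' distribution of the rank sum (computed by convolution, valid under ties);
#' beyond that a normal approximation with continuity and tie correction is
#' used.
#'
#' @param a,b Numeric vectors of equal length.
#' @return List with `statistic` (rank sum of positive differences, `V`),
#'   `p_value`, `n_used` (pairs after zero removal), `n_dropped` and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  d <- b - a
  dropped <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                n_dropped = dropped, method = "degenerate"))
  }
  if (n < 5L)
    warning("fewer than 5 non-zero differences; the test has almost no power")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    ranks2 <- as.integer(round(2 * r))
    p <- signed_rank_exact_p(ranks2, as.integer(round(2 * V)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = V, p_value = p, n_used = n, n_dropped = dropped,
       method = method)
}

#' Holm step-down adjustment of p-values
#'
#' The i-th smallest p-value is multiplied by `m - i + 1`, the running
#' maximum is enforced and results are capped at 1, returned in input order.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Count-based Bayesian signed-rank test with a rope
#'
#' Paired differences `b - a` are counted into three bins — below the rope
#' (`b - a < rope_min`), inside it, and above (`b - a > rope_max`). A
#' Dirichlet posterior is built from the counts with a prior pseudocount
#' placed in the rope (practical equivalence as the skeptical prior, and a
#' guard against degenerate zero-count posteriors), and `n_samples` triplets
#' `(P(left), P(rope), P(right))` are drawn from it. The reported
#' probabilities are the fractions of sampled triplets in which each
#' coordinate is the maximum (ties split evenly); the expected coordinates
#' are also returned.
#'
#' @param a,b Numeric vectors of equal length.
#' @param rope_min,rope_max Rope bounds (default `[-0.01, 0.01]` on the Kappa
#'   scale).
#' @param n_samples Posterior draws (default 2000).
#' @param prior_pseudocount Prior mass in the rope (default 1).
#' @param seed Integer seed.
#' @return An object of class `bayesian_signed_rank`: `p_left`, `p_rope`,
#'   `p_right` (fraction-where-max), `expected` (posterior mean triplet),
#'   `counts`, rope bounds and the `n_samples x 3` matrix of
#'   `sampled_triplets`.
#' @export
bayesian_signed_rank <- function(a, b, rope_min = -0.01, rope_max = 0.01,
                                 n_samples = 2000L, prior_pseudocount = 1,
                                 seed = 1L) {
  if (length(a) == 0L || length(b) == 0L) stop("empty series")
  if (length(a) != length(b)) stop("series lengths differ")
  if (rope_min > rope_max) stop("rope_min exceeds rope_max")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  d <- b - a
  counts <- c(left = sum(d < rope_min),
              rope = sum(d >= rope_min & d <= rope_max),
              right = sum(d > rope_max))
  alpha <- counts + c(0, prior_pseudocount, 0)
  rng <- local_rng(seed)
  g <- matrix(rng$rgamma(3L * n_samples, shape = rep(alpha,
                                                     each = n_samples)),
              n_samples, 3L)
  triplets <- g / rowSums(g)
  colnames(triplets) <- c("p_left", "p_rope", "p_right")
  maxes <- triplets == apply(triplets, 1L, max)
  win <- maxes / rowSums(maxes)  # ties split evenly
  probs <- colMeans(win)
  structure(list(p_left = probs[[1L]], p_rope = probs[[2L]],
                 p_right = probs[[3L]],
                 expected = colMeans(triplets),
                 counts = counts, rope_min = rope_min, rope_max = rope_max,
                 sampled_triplets = triplets),
            class = "bayesian_signed_rank")
}

#' @export
print.bayesian_signed_rank <- function(x, ...) {
  cat(sprintf("Bayesian signed-rank, rope [%g, %g]\n", x$rope_min,
              x$rope_max))
  cat(sprintf("Counts: left %d, rope %d, right %d\n", x$counts[1L],
              x$counts[2L], x$counts[3L]))
  cat(sprintf("P(b - a < 0) = %.3f, P(b - a ~ 0) = %.3f, P(b - a > 0) = %.3f\n",
              x$p_left, x$p_rope, x$p_right))
  invisible(x)
}

#' Map a probability triplet to barycentric heatmap coordinates
#'
#' The simplex point `(p_left, p_rope, p_right)` is placed in an equilateral
#' triangle with the left vertex for `b - a < 0` at the origin, the right
#' vertex for `b - a > 0` at `(1, 0)` and the rope vertex at the top
#' `(1/2, sqrt(3)/2)`.
#'
#' @param triplet Non-negative numeric vector of length 3 summing to 1,
#'   ordered `(left, rope, right)`; or a matrix of such rows.
#' @return Numeric `(x, y)` point, or an `n x 2` matrix.
#' @export
barycentric_coordinates <- function(triplet) {
  v <- rbind(left = c(0, 0), rope = c(0.5, sqrt(3) / 2), right = c(1, 0))
  one <- function(t3) {
    if (length(t3) != 3L || any(t3 < -1e-12) || abs(sum(t3) - 1) > 1e-9)
      stop("triplet must be non-negative and sum to 1")
    drop(t3 %*% v)
  }
  if (is.matrix(triplet)) t(apply(triplet, 1L, one)) else one(triplet)
}

#' @export
plot.bayesian_signed_rank <- function(x, ...) {
  pts <- barycentric_coordinates(x$sampled_triplets)
  graphics::plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.05, 0.95),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", ...)
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2), c(0, 0))
  graphics::lines(tri)
  dens <- grDevices::densCols(pts,
                              colramp = grDevices::colorRampPalette(
                                c("red", "orange", "yellow", "white")))
  graphics::points(pts, pch = 16, cex = 0.4, col = dens)
  graphics::text(c(-0.02, 1.02, 0.5), c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                 c("b - a < 0", "b - a > 0", "rope"))
  invisible(x)
}

#' Full comparison of several methods
#'
#' Runs the Friedman omnibus first; only when it rejects (p below `alpha`)
#' are the pairwise Wilcoxon signed-rank tests computed and Holm-adjusted,
#' together with the pairwise Bayesian signed-rank results.
#'
#' @param values Numeric matrix, observations x methods, with column names.
#' @param rope_min,rope_max Rope for the Bayesian tests.
#' @param n_samples Posterior draws per pair.
#' @param alpha Omnibus significance gate (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `comparison_report`: the Friedman result, a
#'   data frame `pairwise` (raw and Holm-adjusted Wilcoxon p-values plus the
#'   three Bayesian probabilities per pair; `NULL` when the gate fails) and
#'   the list of `bayesian` objects for plotting.
#' @export
compare_methods <- function(values, rope_min = -0.01, rope_max = 0.01,
                            n_samples = 2000L, alpha = 0.05, seed = 1L) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("method", seq_len(ncol(values)))
  fr <- friedman_test(values)
  pairwise <- NULL
  bayes <- list()
  if (fr$p_value < alpha) {
    pairs <- utils::combn(ncol(values), 2L)
    rows <- vector("list", ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
      a <- values[, i1]; b <- values[, i2]
      w <- wilcoxon_signed_rank(a, b)
      bs <- bayesian_signed_rank(a, b, rope_min, rope_max, n_samples,
                                 seed = derive_seed(seed, paste0("pair", j)))
      bayes[[paste(colnames(values)[c(i1, i2)], collapse = " vs ")]] <- bs
      rows[[j]] <- data.frame(
        a = colnames(values)[i1], b = colnames(values)[i2],
        wilcoxon_p = w$p_value, p_left = bs$p_left, p_rope = bs$p_rope,
        p_right = bs$p_right, stringsAsFactors = FALSE)
    }
    pairwise <- do.call(rbind, rows)
    pairwise$holm_p <- holm_adjust(pairwise$wilcoxon_p)
    pairwise <- pairwise[, c("a", "b", "wilcoxon_p", "holm_p",
                             "p_left", "p_rope", "p_right")]
  }
  structure(list(friedman = fr, pairwise = pairwise, bayesian = bayes,
                 rope = c(rope_min, rope_max), alpha = alpha,
                 methods = colnames(values), n_observations = nrow(values)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "Friedman test: chi-square = %.4f, df = %d, p = %.3g (%d obs, %d methods)\n",
    x$friedman$statistic, x$friedman$df, x$friedman$p_value,
    x$n_observations, length(x$methods)))
  if (is.null(x$pairwise)) {
    cat("Omnibus not significant at alpha =", x$alpha,
        "- post-hoc tests not run\n")
  } else {
    cat(sprintf("Post-hoc pairwise tests (rope [%g, %g]):\n", x$rope[1L],
                x$rope[2L]))
    print(x$pairwise, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Write a comparison report and its triplet clouds as text
#'
#' @param x A `comparison_report`.
#' @param dir Output directory (created if needed); writes `report.txt`,
#'   `pairwise.tsv` and one `triplets_<pair>.tsv` per Bayesian comparison.
#' @export
write_comparison_report <- function(x, dir) {
  stopifnot(inherits(x, "comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sink(file.path(dir, "report.txt")); print(x); sink()
  if (!is.null(x$pairwise))
    utils::write.table(x$pairwise, file.path(dir, "pairwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(x$bayesian)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    utils::write.table(x$bayesian[[nm]]$sampled_triplets,
                       file.path(dir, paste0("triplets_", safe, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
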