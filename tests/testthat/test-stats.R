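test_that("Friedman test handles complete agreement and complete ties", {
  same <- matrix(rep(c(1, 2, 3), each = 6L), 6L, 3L)
  tied <- friedman_test(matrix(5, 4L, 3L))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)

  # strictly ordered columns in every observation, n = 5, k = 3:
  # rank sums (5, 10, 15) give 12/(n k (k+1)) * sum Rj^2 - 3 n (k+1) = 10
  ordered <- matrix(c(rep(0.1, 5), rep(0.5, 5), rep(0.9, 5)), 5L, 3L)
  fr <- friedman_test(ordered)
  expect_equal(fr$statistic, 10)
  expect_identical(fr$df, 2L)
  expect_equal(fr$p_value, pchisq(10, 2L, lower.tail = FALSE))
})

test_that("Friedman agrees with the reference implementation when tie-free", {
  rng <- evobci:::local_rng(55)
  for (rep in 1:20) {
    m <- matrix(rng$rnorm(8L * 4L), 8L, 4L)
    fr <- friedman_test(m)
    ref <- stats::friedman.test(m)
    expect_equal(fr$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(fr$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Friedman statistic ignores row-level location shifts", {
  rng <- evobci:::local_rng(56)
  m <- matrix(rng$rnorm(24L), 8L, 3L)
  shifted <- m; shifted[3L, ] <- shifted[3L, ] + 100
  expect_equal(friedman_test(m)$statistic,
               friedman_test(shifted)$statistic)
  expect_error(friedman_test(m[1L, , drop = FALSE]), ">= 2")
})

test_that("exact signed-rank p-values match full sign enumeration", {
  # n = 5, all differences positive: two-sided p = 2/32
  all_pos <- wilcoxon_signed_rank(rep(0, 5L), c(1, 2, 3, 4, 5))
  expect_identical(all_pos$method, "exact")
  expect_equal(all_pos$p_value, 0.0625)

  rng <- evobci:::local_rng(60)
  for (n in 5:10) {
    for (rep in 1:10) {
      a <- rng$rnorm(n)
      b <- a + rng$rnorm(n, 0, 1)
      # occasional exact ties in |differences| via rounding
      b <- round(b, 1L); a <- round(a, 1L)
      keep <- a != b
      if (sum(keep) < 5L) next
      res <- wilcoxon_signed_rank(a, b)
      expect_equal(res$p_value, wilcoxon_enum_p((b - a)[keep]),
                   tolerance = 1e-10, info = paste("n =", n))
    }
  }
})

test_that("signed-rank edge conventions: zeros dropped, antisymmetry,
           reference agreement", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_warning(res <- wilcoxon_signed_rank(a, a), "zero")
  expect_equal(res$p_value, 1)
  expect_identical(res$n_dropped, 6L)

  # antisymmetric differences put the statistic at its mean n(n+1)/4
  anti <- suppressWarnings(
    wilcoxon_signed_rank(c(0, 0, 0, 0), c(1, -1, 2, -2)))
  expect_equal(anti$statistic, 4 * 5 / 4)

  rng <- evobci:::local_rng(61)
  for (rep in 1:10) {
    d <- rng$rnorm(8L)
    ours <- wilcoxon_signed_rank(numeric(8L), d)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }

  # large-sample branch stays close to the reference normal approximation
  d <- rng$rnorm(40L)
  big <- wilcoxon_signed_rank(numeric(40L), d)
  ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                             correct = TRUE))
  expect_identical(big$method, "normal")
  expect_equal(big$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  p <- c(0.3, 0.001, 0.06, 0.02)
  adj <- holm_adjust(p)
  reordered <- holm_adjust(rev(p))
  expect_equal(adj, rev(reordered))     # order invariance
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Bayesian signed-rank posterior matches a quadrature oracle", {
  # construct series with counts (left, rope, right) = (2, 5, 13)
  d <- c(rep(-1, 2L), rep(0, 5L), rep(1, 13L))
  res <- bayesian_signed_rank(numeric(20L), d, rope_min = -0.1,
                              rope_max = 0.1, n_samples = 100000L,
                              prior_pseudocount = 1, seed = 9L)
  expect_identical(unname(res$counts), c(2L, 5L, 13L))
  oracle <- dirichlet_max_probs(c(2, 6, 13))
  expect_equal(c(res$p_left, res$p_rope, res$p_right), oracle,
               tolerance = 0.01)
  expect_equal(res$p_left + res$p_rope + res$p_right, 1, tolerance = 1e-9)
  expect_true(all(abs(rowSums(res$sampled_triplets) - 1) < 1e-9))
  expect_true(all(res$sampled_triplets >= 0))
})

test_that("Bayesian test limits: domination, equality, approximate
           symmetry", {
  a <- rep(0.5, 12L)
  b <- a + 0.3
  dom <- bayesian_signed_rank(a, b, n_samples = 5000L, seed = 2L)
  expect_gt(dom$p_right, 0.95)

  eq <- bayesian_signed_rank(a, a, n_samples = 5000L, seed = 3L)
  expect_gt(eq$p_rope, 0.95)

  rng <- evobci:::local_rng(70)
  x <- rng$rnorm(15L); y <- x + rng$rnorm(15L, 0.05, 0.2)
  f <- bayesian_signed_rank(x, y, n_samples = 40000L, seed = 4L)
  r <- bayesian_signed_rank(y, x, n_samples = 40000L, seed = 4L)
  expect_lt(abs(f$p_left - r$p_right), 0.02)
  expect_lt(abs(f$p_rope - r$p_rope), 0.02)
  expect_error(bayesian_signed_rank(numeric(0L), numeric(0L)), "empty")
  expect_error(bayesian_signed_rank(1:3, 1:3, rope_min = 1, rope_max = 0),
               "rope")
})

test_that("barycentric mapping hits vertices, centroid, and is affine", {
  expect_equal(barycentric_coordinates(c(1, 0, 0)), c(0, 0))
  expect_equal(barycentric_coordinates(c(0, 0, 1)), c(1, 0))
  expect_equal(barycentric_coordinates(c(0, 1, 0)), c(0.5, sqrt(3) / 2))
  expect_equal(barycentric_coordinates(c(1, 1, 1) / 3),
               c(0.5, sqrt(3) / 6), tolerance = 1e-12)
  t1 <- c(0.2, 0.5, 0.3); t2 <- c(0.6, 0.1, 0.3)
  expect_equal(barycentric_coordinates((t1 + t2) / 2),
               (barycentric_coordinates(t1) + barycentric_coordinates(t2)) / 2)
  expect_error(barycentric_coordinates(c(0.5, 0.6, 0.2)), "sum to 1")
})

test_that("compare_methods gates post-hocs on the omnibus and covers all
           pairs", {
  same <- matrix(rep(c(0.5, 0.6, 0.7, 0.8), 2L), 4L, 2L)
  colnames(same) <- c("m1", "m2")
  rep0 <- compare_methods(same)
  expect_equal(rep0$friedman$p_value, 1)
  expect_null(rep0$pairwise)

  rng <- evobci:::local_rng(80)
  n <- 12L
  base <- rng$runif(n, 0.4, 0.6)
  vals <- cbind(weak = base - 0.15 + rng$rnorm(n, 0, 0.01),
                mid = base,
                strong = base + 0.15 + rng$rnorm(n, 0, 0.01))
  rep1 <- compare_methods(vals, seed = 5L)
  expect_lt(rep1$friedman$p_value, 0.05)
  expect_identical(nrow(rep1$pairwise), 3L)  # C(3, 2) pairs
  dom <- rep1$pairwise[rep1$pairwise$a == "weak" &
                         rep1$pairwise$b == "strong", ]
  expect_gt(dom$p_right, 0.95)
  expect_true(all(rep1$pairwise$holm_p >= rep1$pairwise$wilcoxon_p))
})
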