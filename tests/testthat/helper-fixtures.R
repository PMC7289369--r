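# Shared fixtures and tiny independent oracles, all built in code.

# deterministic 16-sample signal used for the frozen wavelet oracle
oracle_signal <- function() {
  t <- 1:16
  round(sin(t) + 0.5 * cos(3 * t), 6)
}

# small separable 2-class, 2-feature matrix in [0, 1]
toy_separable <- function(n_per_class = 40, seed = 1) {
  rng <- evobci:::local_rng(seed)
  x <- rbind(matrix(rng$rnorm(2 * n_per_class, -2, 0.5), n_per_class, 2),
             matrix(rng$rnorm(2 * n_per_class, 2, 0.5), n_per_class, 2))
  x <- (x - min(x)) / (max(x) - min(x))
  feature_matrix(x, rep(0:1, each = n_per_class))
}

# small 3-class matrix with planted structure, for GA/network tests
toy_three_class <- function(n = 60, p = 16, seed = 5) {
  generate_feature_patterns(n, p, n_informative = 4, effect_size = 2,
                            n_classes = 3, seed = seed)$matrix
}

# Eq-style convolution oracle: H[i] = sum_u F[u] G[i - u], F indexed -k..k,
# valid positions only
conv_brute <- function(g, f) {
  k <- (length(f) - 1L) / 2L
  n <- length(g)
  vapply((k + 1L):(n - k), function(i)
    sum(vapply(-k:k, function(u) f[u + k + 1L] * g[i - u], numeric(1))),
    numeric(1))
}

# scalar-by-scalar GRU recurrence oracle
gru_brute <- function(x_t, h_prev, w) {
  H <- length(h_prev)
  sig <- function(v) 1 / (1 + exp(-v))
  h_new <- numeric(H)
  r <- numeric(H); z <- numeric(H)
  for (j in seq_len(H)) {
    r[j] <- sig(sum(w$W_r[j, ] * x_t) + sum(w$U_r[j, ] * h_prev) + w$b_r[j])
    z[j] <- sig(sum(w$W_z[j, ] * x_t) + sum(w$U_z[j, ] * h_prev) + w$b_z[j])
  }
  for (j in seq_len(H)) {
    cand <- tanh(sum(w$W_h[j, ] * x_t) +
                   sum(w$U_h[j, ] * (r * h_prev + w$b_h)))
    h_new[j] <- z[j] * h_prev[j] + (1 - z[j]) * cand
  }
  h_new
}

# independent Cohen's kappa: explicit marginal enumeration
kappa_brute <- function(m) {
  total <- sum(m)
  p0 <- sum(diag(m)) / total
  pc <- 0
  for (c in seq_len(nrow(m)))
    pc <- pc + (sum(m[c, ]) / total) * (sum(m[, c]) / total)
  (p0 - pc) / (1 - pc)
}

# exact two-sided signed-rank p by full enumeration of sign assignments
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

random_confusion <- function(rng, C = 3, max_count = 30) {
  matrix(rng$sample_int(max_count, C * C, replace = TRUE), C, C)
}

# grid quadrature over the 2-simplex for P(coordinate i is the maximum)
# under a Dirichlet(alpha) density
dirichlet_max_probs <- function(alpha, steps = 1200L) {
  h <- 1 / steps
  p1 <- seq(h / 2, 1 - h / 2, by = h)
  grid <- expand.grid(p1 = p1, p2 = p1)
  grid <- grid[grid$p1 + grid$p2 < 1, ]
  p3 <- 1 - grid$p1 - grid$p2
  dens <- grid$p1^(alpha[1] - 1) * grid$p2^(alpha[2] - 1) * p3^(alpha[3] - 1)
  amax <- max.col(cbind(grid$p1, grid$p2, p3))
  vapply(1:3, function(i) sum(dens[amax == i]), numeric(1)) / sum(dens)
}
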