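test_that("structure initialization concentrates near mid-range within
           bounds", {
  pop <- init_structure_population("cnn", 10000L, 3600L, rng = 2L)
  filters <- vapply(pop, `[[`, numeric(1), 1L)
  sizes <- vapply(pop, `[[`, numeric(1), 2L)
  expect_true(all(filters >= 1 & filters <= 250))
  expect_true(all(sizes >= 1 & sizes <= 19))
  expect_true(all(sizes %% 2 == 1))
  expect_equal(mean(filters), 125.5, tolerance = 2)     # mid 125.5, SE ~0.4
  expect_equal(mean(sizes), 10, tolerance = 0.5)        # mid 10, forced odd
  expect_equal(sd(sizes), 3, tolerance = 0.6)           # range/6

  ff <- init_structure_population("ffnn", 500L, 200L, rng = 3L)
  expect_true(all(lengths(ff) %in% 1:2))
  expect_true(any(lengths(ff) == 1L) && any(lengths(ff) == 2L))
  expect_true(all(unlist(ff) >= 1))

  expect_identical(init_structure_population("rnn", 20L, 100L, rng = 5L),
                   init_structure_population("rnn", 20L, 100L, rng = 5L))
})

test_that("single-point crossover mixes parents at a cut", {
  rng <- evobci:::local_rng(6)
  expect_identical(single_point_crossover(c(1, 2), c(10, 20), rng),
                   c(1, 20))
  expect_identical(single_point_crossover(c(3, 4), c(3, 4), rng), c(3, 4))
  for (rep in 1:50) {
    a <- rng$rnorm(4L); b <- rng$rnorm(4L)
    child <- single_point_crossover(a, b, rng)
    expect_true(all(child %in% c(a, b)))  # every gene from a parent
  }
  # degenerate length-1 genome: copy of one parent
  picks <- replicate(100, single_point_crossover(1, 2, rng))
  expect_setequal(unique(picks), c(1, 2))
  expect_error(single_point_crossover(c(1, 2), 3, rng), "mismatch")
})

test_that("Gaussian mutation is mean-preserving and respects bounds", {
  bounds <- evobci:::structure_bounds("cnn", 3600L)
  rng <- evobci:::local_rng(14)
  mutated <- replicate(10000, gaussian_mutation(c(100, 9), 0.1, bounds,
                                                rng)[1L])
  changed <- mutated[mutated != 100]
  expect_equal(mean(changed), 100, tolerance = 3 * 10 / sqrt(length(changed)))

  at_cap <- gaussian_mutation(c(250, 9), 0.1, bounds,
                              evobci:::local_rng(1))
  expect_lte(at_cap[1L], 250)
  for (rep in 1:200) {
    g <- gaussian_mutation(c(100, 19), 0.4, bounds, rng)
    expect_true(g[2L] %% 2 == 1 && g[2L] >= 1 && g[2L] <= 19)
  }
  expect_error(gaussian_mutation(c(1, 1), 0, bounds, rng), "sigma")
})

test_that("midpoint crossover follows the half-and-half rule", {
  rng <- evobci:::local_rng(2)
  expect_identical(midpoint_crossover(c(80, 40), c(30), rng), c(80, 30))
  expect_identical(midpoint_crossover(c(64), c(100), rng), c(64, 100))
  expect_identical(midpoint_crossover(c(50, 20), c(50, 20), rng), c(50, 20))
  expect_lte(length(midpoint_crossover(c(9, 9), c(8, 8), rng)), 2L)
})

test_that("FFNN mutation either rescales one layer or the whole network", {
  rng <- evobci:::local_rng(20)
  for (rep in 1:200) {
    g <- c(120, 60)
    m <- ffnn_mutation(g, 0.05, rng)
    expect_true(all(m >= 1))
    n_changed <- sum(m != g)
    if (n_changed == 2L)  # scaling branch: ratio preserved up to rounding
      expect_equal(m[1L] / m[2L], 2, tolerance = 0.1)
  }
  expect_true(all(ffnn_mutation(c(1, 1), 3, rng) >= 1))  # floor
})

test_that("learning genomes stay within their ranges and decode cleanly", {
  rng <- evobci:::local_rng(44)
  bounds <- evobci:::learning_bounds("ffnn")
  for (rep in 1:300) {
    g <- c(rng$runif(1, 1e-4, 1), rng$sample_int(200L, 1L),
           rng$runif(1, 0, 0.9))
    tp <- decode_learning("ffnn", g)
    expect_true(tp$learning_rate > 0 && tp$learning_rate <= 1)
    expect_true(tp$epochs >= 1L && tp$epochs <= 200L)
    expect_true(tp$dropout_rate >= 0 && tp$dropout_rate < 1)
  }
})

test_that("the structure search returns a feasible, elitism-consistent
           winner", {
  fm <- toy_three_class(n = 60L, p = 16L)
  res <- optimize_structure("ffnn", fm,
                            config = ga_config(4L, 2L, seed = 8L),
                            step1_params = training_params(0.1, 15L))
  expect_s3_class(res$best_spec, "ffnn_spec")
  expect_true(length(res$best_spec$hidden_widths) %in% 1:2)
  expect_gte(res$ga$best_individual$fitness,
             res$ga$best_fitness_per_generation[1L])
  # every survivor decodes within bounds
  for (ind in res$ga$final_population) {
    spec <- decode_structure("ffnn", ind$genome, 16L, 3L)
    expect_true(all(spec$hidden_widths >= 1L))
  }
})

test_that("the learning search keeps the structure frozen and honors the
           incumbent", {
  fm <- toy_three_class(n = 60L, p = 16L)
  frozen <- c(12)
  res <- optimize_learning("rnn", frozen, fm,
                           config = ga_config(4L, 1L, seed = 13L),
                           incumbent = training_params(0.1, 10L))
  expect_identical(frozen, c(12))
  expect_true(res$best_params$epochs >= 1L && res$best_params$epochs <= 200L)
  # elitism + incumbent: result at least as fit as the incumbent's own eval
  inc_fit <- res$ga$best_fitness_per_generation[1L]
  expect_gte(res$ga$best_individual$fitness, inc_fit)
})

test_that("the two-step procedure is deterministic and yields a trainable
           spec", {
  fm <- toy_three_class(n = 60L, p = 16L)
  run <- function() two_step_optimize(
    "ffnn", fm,
    structure_config = ga_config(4L, 1L, seed = 3L),
    learning_config = ga_config(4L, 1L, seed = 4L),
    step1_params = training_params(0.1, 10L))
  m1 <- run(); m2 <- run()
  expect_identical(m1$structure_genes, m2$structure_genes)
  expect_identical(m1$learning_genes, m2$learning_genes)

  spec <- decode_structure(m1$family, m1$structure_genes, 16L, 3L,
                           m1$training$dropout_rate)
  trained <- train_model(build_model(spec), fm, m1$training)
  expect_length(predict(trained, fm), nrow(fm$values))
})

test_that("model specs round-trip through YAML", {
  ms <- baseline_spec("ffnn", c(100, 40),
                      training_params(0.05, 120L, dropout_rate = 0.2))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(ms, path)
  back <- read_model_spec(path)
  expect_identical(back$family, "ffnn")
  expect_equal(back$structure_genes, c(100, 40))
  expect_equal(back$training$learning_rate, 0.05)
  expect_identical(back$training$epochs, 120L)
  expect_equal(back$training$dropout_rate, 0.2)
})
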