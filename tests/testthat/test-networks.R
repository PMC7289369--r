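test_that("activation functions match their definitions and are monotone", {
  expect_equal(activation("leaky_relu", -1), -0.01)
  expect_equal(activation("relu", c(-2, 3)), c(0, 3))
  expect_equal(activation("elu", 0), 0)
  expect_equal(activation("elu", -1e-9), expm1(-1e-9))  # continuous at 0
  expect_equal(activation("tanh", 0.3), tanh(0.3))
  grid <- seq(-4, 4, by = 0.05)
  for (nm in c("tanh", "relu", "leaky_relu", "elu"))
    expect_false(is.unsorted(activation(nm, grid)))
  expect_error(activation("swish", 1), "unknown")
})

test_that("valid convolution equals the double-loop definition", {
  rng <- evobci:::local_rng(8)
  for (rep in 1:100) {
    n <- 10L + rng$sample_int(40L, 1L)
    fs <- c(1L, 3L, 5L, 7L)[rng$sample_int(4L, 1L)]
    g <- rng$rnorm(n); f <- rng$rnorm(fs)
    expect_equal(conv1d_valid(g, f), conv_brute(g, f), tolerance = 1e-10)
  }
  x <- rnorm(3600)
  expect_length(conv1d_valid(x, rnorm(5)), 3596L)
  expect_equal(conv1d_valid(x, c(0, 1, 0)), x[2:3599])  # identity kernel
  expect_error(conv1d_valid(rnorm(10), rnorm(4)), "odd")
})

zero_gru <- function(H, n_in) {
  list(W_r = matrix(0, H, n_in), U_r = matrix(0, H, H), b_r = numeric(H),
       W_z = matrix(0, H, n_in), U_z = matrix(0, H, H), b_z = numeric(H),
       W_h = matrix(0, H, n_in), U_h = matrix(0, H, H), b_h = numeric(H))
}

test_that("the GRU step matches scalar evaluation of its recurrences", {
  rng <- evobci:::local_rng(12)
  for (rep in 1:25) {
    H <- rng$sample_int(6L, 1L); n_in <- rng$sample_int(4L, 1L)
    w <- zero_gru(H, n_in)
    for (nm in names(w)) w[[nm]] <- w[[nm]] + rng$rnorm(length(w[[nm]]), 0, 0.7)
    x <- rng$rnorm(n_in); h <- rng$rnorm(H)
    expect_equal(gru_step(x, h, w), gru_brute(x, h, w), tolerance = 1e-12)
  }
  h0 <- c(0.4, -0.2, 1.1)
  expect_equal(gru_step(c(1, 2), h0, zero_gru(3L, 2L)), 0.5 * h0)
  expect_equal(gru_step(numeric(2L), numeric(3L), zero_gru(3L, 2L)),
               numeric(3L))
  expect_error(gru_step(1, numeric(3L), zero_gru(3L, 2L)), "W_r")
})

test_that("parameter counts match an element-count oracle for all families", {
  specs <- list(cnn_spec(7L, 5L, 40L, 3L),
                ffnn_spec(c(11L, 6L), 20L, 3L),
                ffnn_spec(9L, 20L, 2L),
                rnn_spec(5L, 30L, 3L))
  for (s in specs) {
    p <- evobci:::init_params(s, seed = 1L)
    expect_identical(count_params(s), sum(vapply(p, length, integer(1))),
                     info = s$family)
  }
  # printed flattened-width arithmetic for the reference CNN
  big <- cnn_spec(130L, 5L, 3600L, 3L)
  expect_identical((3600L - 5L + 1L) * 130L, 467480L)
  expect_identical(count_params(big), 130L * 5L + 130L + 467480L * 3L + 3L)
})

test_that("structure bounds are enforced at construction", {
  expect_error(cnn_spec(300L, 5L, 100L, 3L), "1..250")
  expect_error(cnn_spec(10L, 4L, 100L, 3L), "odd")
  expect_error(ffnn_spec(c(5L, 5L, 5L), 20L, 3L), "depth")
  expect_error(rnn_spec(61L, 20L, 3L), "1..60")
  expect_error(training_params(epochs = 201L), "epochs")
  expect_error(training_params(learning_rate = 0), "learning_rate")
})

numeric_gradient_check <- function(spec, n = 6L, lr = 0.05) {
  rng <- evobci:::local_rng(33)
  X <- matrix(rng$runif(n * spec$n_inputs), n, spec$n_inputs)
  y <- rep_len(0:(spec$n_classes - 1L), n)
  fm <- feature_matrix(X, y)
  m0 <- train_model(build_model(spec), fm,
                    training_params(lr, 0L, seed = 77L))  # init only
  loss_at <- function(params) {
    m <- m0; m$params <- params
    P <- predict(m, X, type = "prob")
    -mean(log(P[cbind(seq_len(n), y + 1L)]))
  }
  m1 <- train_model(m0, fm, training_params(lr, 1L, batch_size = n,
                                            seed = 78L))
  eps <- 1e-6
  for (nm in names(m0$params)) {
    analytic <- (m0$params[[nm]] - m1$params[[nm]]) / lr
    numeric <- m0$params[[nm]]
    for (i in seq_along(numeric)) {
      pp <- m0$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m0$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      numeric[i] <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    }
    expect_equal(unname(as.vector(analytic)), unname(as.vector(numeric)),
                 tolerance = 1e-4,
                 info = paste(spec$family, nm))
  }
}

test_that("one SGD step equals the numerical gradient (all families)", {
  numeric_gradient_check(ffnn_spec(c(4L, 3L), 5L, 3L))
  numeric_gradient_check(cnn_spec(2L, 3L, 8L, 3L))
  numeric_gradient_check(rnn_spec(3L, 6L, 2L))
})

test_that("training fits separable data and its loss decreases", {
  fm <- toy_separable(30L, seed = 6)
  m <- train_model(build_model(ffnn_spec(8L, 2L, 2L)), fm,
                   training_params(0.1, 200L, seed = 3L))
  expect_equal(mean(predict(m, fm) == fm$labels), 1)
  expect_lt(tail(m$history$loss, 1L), m$history$loss[1L])

  # epochs = 0 leaves parameters untouched
  again <- train_model(m, fm, training_params(0.1, 0L, seed = 9L))
  expect_identical(again$params, m$params)
})

test_that("prediction is a proper, deterministic softmax classifier", {
  fm <- toy_three_class(n = 45L, p = 12L)
  m <- train_model(build_model(cnn_spec(3L, 3L, 12L, 3L)), fm,
                   training_params(0.1, 20L, seed = 5L))
  P <- predict(m, fm, type = "prob")
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
  expect_identical(predict(m, fm), predict(m, fm))
  expect_error(predict(m, fm$values[, 1:5]), "width")

  # single-class training data collapses onto that class
  one_class <- feature_matrix(matrix(runif(40), 10L, 4L), rep(1L, 10L))
  mc <- train_model(build_model(ffnn_spec(4L, 4L, 2L)), one_class,
                    training_params(0.2, 60L, seed = 2L))
  expect_true(all(predict(mc, one_class) == 1L))
})

test_that("GRU classifier learns a short-sequence task", {
  fm <- toy_three_class(n = 60L, p = 12L)
  m <- train_model(build_model(rnn_spec(10L, 12L, 3L)), fm,
                   training_params(0.2, 80L, seed = 4L))
  expect_gt(mean(predict(m, fm) == fm$labels), 0.5)  # well above 1/3 chance
})
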