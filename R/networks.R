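#' Shallow neural classifier families
#'
#' Three purposely shallow architectures share a softmax output head trained
#' by backpropagation with plain stochastic gradient descent:
#' a feed-forward network with one or two dense hidden layers (ELU default,
#' optional dropout), a one-dimensional convolutional network with a single
#' valid-mode convolutional layer (ReLU default) flattened into the output
#' layer, and a recurrent network with one GRU layer reading the feature
#' vector as a univariate sequence (ReLU default on the final hidden state).
#' Shallowness is deliberate: motor-imagery feature sets are small (on the
#' order of a hundred patterns), and deeper stacks overfit long before they
#' help.
#'
#' @name networks
NULL

#' Activation functions
#'
#' `relu(x) = max(0, x)`; `leaky_relu` uses slope 0.01 for `x <= 0`;
#' `elu` replaces the negative part with `exp(x) - 1`; `tanh` is standard.
#'
#' @param name One of `"tanh"`, `"relu"`, `"leaky_relu"`, `"elu"`.
#' @param x Numeric vector/matrix.
#' @return Element-wise activation values.
#' @export
activation <- function(name, x) {
  switch(name,
    tanh = tanh(x),
    relu = pmax(x, 0),
    leaky_relu = ifelse(x > 0, x, 0.01 * x),
    elu = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
    stop("unknown activation: '", name, "'")
  )
}

activation_grad <- function(name, x) {
  switch(name,
    tanh = 1 - tanh(x)^2,
    relu = (x > 0) + 0,
    leaky_relu = ifelse(x > 0, 1, 0.01),
    elu = ifelse(x > 0, 1, exp(pmin(x, 0))),
    stop("unknown activation: '", name, "'")
  )
}

#' Valid-mode one-dimensional convolution
#'
#' The discrete convolution `H[i] = sum_u F[u] * G[i - u]` with the filter
#' `F` indexed over `-k..k`, restricted to positions where the filter fits
#' entirely inside the input (border values are discarded): an input of
#' length `n` and a filter of length `2k + 1` give an output of length
#' `n - 2k`. The filter center must align with an input position, hence the
#' odd length.
#'
#' @param input Numeric vector of length `n` (the observation `G`).
#' @param filter Numeric vector of odd length `2k + 1 <= n`, ordered
#'   `F[-k], ..., F[k]`.
#' @return Numeric vector of length `n - 2k`.
#' @export
conv1d_valid <- function(input, filter) {
  fs <- length(filter)
  if (fs %% 2L == 0L) stop("filter length must be odd")
  n <- length(input)
  if (fs > n) stop("filter longer than input")
  L <- n - fs + 1L
  out <- numeric(L)
  # H[i] = sum_u F[u] G[i-u] equals sliding correlation with rev(filter)
  for (j in seq_len(fs))
    out <- out + filter[fs + 1L - j] * input[j:(j + L - 1L)]
  out
}

#' One GRU recurrence step
#'
#' Computes the reset gate `r = sigmoid(W_r x + U_r h + b_r)`, the update
#' gate `z = sigmoid(W_z x + U_z h + b_z)`, the candidate state
#' `h~ = tanh(W_h x + U_h (r * h + b_h))` (the bias enters inside the
#' recurrent product) and the new state `h' = z * h + (1 - z) * h~`.
#'
#' @param x_t Input vector (length `n_in`).
#' @param h_prev Previous hidden state (length `H`).
#' @param weights List with `W_r`, `W_z`, `W_h` (`H x n_in`), `U_r`, `U_z`,
#'   `U_h` (`H x H`) and `b_r`, `b_z`, `b_h` (length `H`).
#' @return The new hidden state, a numeric vector of length `H`.
#' @export
gru_step <- function(x_t, h_prev, weights) {
  H <- length(h_prev)
  w <- weights
  for (nm in c("W_r", "W_z", "W_h")) {
    if (nrow(w[[nm]]) != H || ncol(w[[nm]]) != length(x_t))
      stop(nm, " must be ", H, " x ", length(x_t))
  }
  for (nm in c("U_r", "U_z", "U_h"))
    if (!all(dim(w[[nm]]) == c(H, H))) stop(nm, " must be ", H, " x ", H)
  sig <- function(v) 1 / (1 + exp(-v))
  r <- sig(drop(w$W_r %*% x_t) + drop(w$U_r %*% h_prev) + w$b_r)
  z <- sig(drop(w$W_z %*% x_t) + drop(w$U_z %*% h_prev) + w$b_z)
  h_tilde <- tanh(drop(w$W_h %*% x_t) + drop(w$U_h %*% (r * h_prev + w$b_h)))
  z * h_prev + (1 - z) * h_tilde
}

#' Network structure specifications
#'
#' Constructors validating the structural bounds of each family: at most 250
#' filters of odd size at most 19 for the CNN; one or two dense hidden layers
#' for the FFNN; at most 60 GRU units for the RNN.
#'
#' @param n_filters Number of convolution filters (1..250).
#' @param filter_size Odd filter length (1..19).
#' @param activation Activation name (CNN/RNN default `"relu"`, FFNN
#'   default `"elu"`).
#' @param n_inputs Input feature count.
#' @param n_classes Number of classes.
#' @return A spec object (`cnn_spec`, `ffnn_spec` or `rnn_spec`), all also
#'   inheriting class `network_spec`.
#' @export
cnn_spec <- function(n_filters, filter_size, n_inputs, n_classes,
                     activation = "relu") {
  n_filters <- as.integer(n_filters); filter_size <- as.integer(filter_size)
  if (n_filters < 1L || n_filters > 250L)
    stop("n_filters must lie in 1..250")
  if (filter_size < 1L || filter_size > 19L || filter_size %% 2L == 0L)
    stop("filter_size must be odd and lie in 1..19")
  if (filter_size > n_inputs) stop("filter_size exceeds input length")
  structure(list(family = "cnn", n_filters = n_filters,
                 filter_size = filter_size, activation = activation,
                 n_inputs = as.integer(n_inputs),
                 n_classes = as.integer(n_classes)),
            class = c("cnn_spec", "network_spec"))
}

#' @rdname cnn_spec
#' @param hidden_widths Integer vector of 1 or 2 hidden-layer widths (>= 1).
#' @param dropout_rate Dropout probability on hidden activations, in `[0, 1)`.
#' @export
ffnn_spec <- function(hidden_widths, n_inputs, n_classes,
                      activation = "elu", dropout_rate = 0) {
  hidden_widths <- as.integer(hidden_widths)
  if (length(hidden_widths) < 1L || length(hidden_widths) > 2L)
    stop("FFNN depth must be 1 or 2 hidden layers")
  if (any(hidden_widths < 1L)) stop("hidden widths must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  structure(list(family = "ffnn", hidden_widths = hidden_widths,
                 activation = activation, dropout_rate = dropout_rate,
                 n_inputs = as.integer(n_inputs),
                 n_classes = as.integer(n_classes)),
            class = c("ffnn_spec", "network_spec"))
}

#' @rdname cnn_spec
#' @param gru_units Number of recurrent units (1..60).
#' @export
rnn_spec <- function(gru_units, n_inputs, n_classes, activation = "relu") {
  gru_units <- as.integer(gru_units)
  if (gru_units < 1L || gru_units > 60L)
    stop("gru_units must lie in 1..60")
  structure(list(family = "rnn", gru_units = gru_units,
                 activation = activation,
                 n_inputs = as.integer(n_inputs),
                 n_classes = as.integer(n_classes)),
            class = c("rnn_spec", "network_spec"))
}

#' Training hyperparameters
#'
#' @param learning_rate Fraction of the measured error used to correct the
#'   weights, in `(0, 1]` (default 0.1, the unoptimized baseline).
#' @param epochs Full passes over the training data, 0..200 (default 60, the
#'   unoptimized baseline; 0 leaves the weights untouched).
#' @param dropout_rate Dropout probability (FFNN only), in `[0, 1)`.
#' @param batch_size Minibatch size for stochastic gradient descent.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return An object of class `training_params`.
#' @export
training_params <- function(learning_rate = 0.1, epochs = 60L,
                            dropout_rate = 0, batch_size = 16L, seed = 1L) {
  epochs <- as.integer(epochs)
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must lie in (0, 1]")
  if (epochs < 0L || epochs > 200L) stop("epochs must lie in 0..200")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "training_params")
}

#' Build an untrained classifier from a structure specification
#'
#' @param spec A `cnn_spec`, `ffnn_spec` or `rnn_spec`.
#' @return An object of class `mi_network` with the spec, a `NULL` parameter
#'   set (filled by [train_model()]) and the total trainable parameter count.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  structure(list(spec = spec, params = NULL, history = NULL,
                 n_params = count_params(spec)),
            class = "mi_network")
}

#' Closed-form trainable parameter count of a specification
#'
#' @param spec A network spec.
#' @return Integer parameter count.
#' @export
count_params <- function(spec) {
  d <- spec$n_inputs; C <- spec$n_classes
  switch(spec$family,
    cnn = {
      L <- d - spec$filter_size + 1L
      spec$n_filters * spec$filter_size + spec$n_filters +
        (L * spec$n_filters) * C + C
    },
    ffnn = {
      w <- spec$hidden_widths
      total <- d * w[1L] + w[1L]
      if (length(w) == 2L) total <- total + w[1L] * w[2L] + w[2L]
      total + w[length(w)] * C + C
    },
    rnn = {
      H <- spec$gru_units
      3L * (H + H * H + H) + H * C + C  # scalar input per step
    }
  )
}

#' @export
print.mi_network <- function(x, ...) {
  s <- x$spec
  desc <- switch(s$family,
    cnn = sprintf("CNN: %d filters of size %d (%s)", s$n_filters,
                  s$filter_size, s$activation),
    ffnn = sprintf("FFNN: hidden widths %s (%s, dropout %.2f)",
                   paste(s$hidden_widths, collapse = "-"), s$activation,
                   s$dropout_rate),
    rnn = sprintf("GRU-RNN: %d units (%s)", s$gru_units, s$activation))
  cat(desc, "\n")
  cat("Inputs:", s$n_inputs, " Classes:", s$n_classes,
      " Trainable parameters:", x$n_params, "\n")
  cat(if (is.null(x$params)) "Untrained\n" else
    sprintf("Trained; final epoch loss %.4f\n",
            utils::tail(x$history$loss, 1)))
  invisible(x)
}

# fan-in-scaled uniform initialization
init_mat <- function(rng, nr, nc, fan_in) {
  lim <- sqrt(6 / max(fan_in, 1))
  matrix(rng$runif(nr * nc, -lim, lim), nr, nc)
}

init_params <- function(spec, seed) {
  rng <- local_rng(seed)
  d <- spec$n_inputs; C <- spec$n_classes
  switch(spec$family,
    ffnn = {
      w <- spec$hidden_widths
      p <- list(W1 = init_mat(rng, d, w[1L], d), b1 = numeric(w[1L]))
      if (length(w) == 2L) {
        p$W2 <- init_mat(rng, w[1L], w[2L], w[1L]); p$b2 <- numeric(w[2L])
      }
      p$Wo <- init_mat(rng, w[length(w)], C, w[length(w)])
      p$bo <- numeric(C)
      p
    },
    cnn = {
      L <- d - spec$filter_size + 1L
      list(F = init_mat(rng, spec$n_filters, spec$filter_size,
                        spec$filter_size),
           bf = numeric(spec$n_filters),
           Wo = init_mat(rng, L * spec$n_filters, C, L * spec$n_filters),
           bo = numeric(C))
    },
    rnn = {
      H <- spec$gru_units
      list(W_r = init_mat(rng, H, 1L, H), U_r = init_mat(rng, H, H, H),
           b_r = numeric(H),
           W_z = init_mat(rng, H, 1L, H), U_z = init_mat(rng, H, H, H),
           b_z = numeric(H),
           W_h = init_mat(rng, H, 1L, H), U_h = init_mat(rng, H, H, H),
           b_h = numeric(H),
           Wo = init_mat(rng, H, C, H), bo = numeric(C))
    }
  )
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward passes returning softmax probabilities (inference mode, no dropout)
forward_probs <- function(spec, p, X) {
  switch(spec$family,
    ffnn = {
      A <- activation(spec$activation, X %*% p$W1 +
                        matrix(p$b1, nrow(X), length(p$b1), byrow = TRUE))
      if (!is.null(p$W2))
        A <- activation(spec$activation, A %*% p$W2 +
                          matrix(p$b2, nrow(A), length(p$b2), byrow = TRUE))
      softmax_rows(A %*% p$Wo + matrix(p$bo, nrow(A), length(p$bo),
                                       byrow = TRUE))
    },
    cnn = {
      flat <- cnn_flat(spec, p, X)$flat
      softmax_rows(flat %*% p$Wo + matrix(p$bo, nrow(flat), length(p$bo),
                                          byrow = TRUE))
    },
    rnn = {
      hT <- gru_forward(spec, p, X)$h
      A <- activation(spec$activation, hT)
      softmax_rows(A %*% p$Wo + matrix(p$bo, nrow(A), length(p$bo),
                                       byrow = TRUE))
    }
  )
}

# conv layer forward shared by train/predict: XS is (m*L) x fs, flat m x (L*nf)
cnn_flat <- function(spec, p, X) {
  m <- nrow(X); fs <- spec$filter_size
  L <- spec$n_inputs - fs + 1L
  XS <- matrix(0, m * L, fs)
  for (j in seq_len(fs))
    XS[, j] <- as.vector(X[, j:(j + L - 1L), drop = FALSE])
  CO <- XS %*% t(p$F) +
    matrix(p$bf, m * L, spec$n_filters, byrow = TRUE)
  A <- activation(spec$activation, CO)
  flat <- matrix(array(A, c(m, L, spec$n_filters)), m, L * spec$n_filters)
  list(XS = XS, CO = CO, A = A, flat = flat, m = m, L = L)
}

# GRU forward over the univariate sequence; keeps per-step quantities for BPTT
gru_forward <- function(spec, p, X, keep = FALSE) {
  m <- nrow(X); d <- ncol(X); H <- spec$gru_units
  h <- matrix(0, m, H)
  sig <- function(v) 1 / (1 + exp(-v))
  store <- if (keep) vector("list", d)
  bh <- matrix(p$b_h, m, H, byrow = TRUE)
  for (t in seq_len(d)) {
    xt <- X[, t]
    r <- sig(xt %o% drop(p$W_r) + h %*% t(p$U_r) +
               matrix(p$b_r, m, H, byrow = TRUE))
    z <- sig(xt %o% drop(p$W_z) + h %*% t(p$U_z) +
               matrix(p$b_z, m, H, byrow = TRUE))
    v <- r * h + bh
    hc <- tanh(xt %o% drop(p$W_h) + v %*% t(p$U_h))
    h_new <- z * h + (1 - z) * hc
    if (keep) store[[t]] <- list(r = r, z = z, hc = hc, h_prev = h, v = v)
    h <- h_new
  }
  list(h = h, store = store)
}

cross_entropy <- function(P, Y) -mean(log(pmax(rowSums(P * Y), 1e-12)))

#' Train a classifier by backpropagation with stochastic gradient descent
#'
#' Minimizes multiclass cross-entropy for exactly `epochs` passes over the
#' training patterns, in shuffled minibatches, at a fixed learning rate.
#' Weight initialization and shuffling are fully determined by
#' `params$seed`.
#'
#' @param model An untrained (or trained) `mi_network` from [build_model()].
#' @param train A [feature_matrix()] whose labels lie in `0..C-1`.
#' @param params A [training_params()].
#' @return The trained `mi_network`, with `history$loss` holding the mean
#'   training loss of each epoch.
#' @export
train_model <- function(model, train, params = training_params()) {
  stopifnot(inherits(model, "mi_network"), inherits(train, "feature_matrix"),
            inherits(params, "training_params"))
  spec <- model$spec
  X <- train$values
  if (ncol(X) != spec$n_inputs)
    stop("feature width ", ncol(X), " does not match model input ",
         spec$n_inputs)
  if (any(train$labels >= spec$n_classes))
    stop("labels exceed the model's class count")
  n <- nrow(X)
  Y <- matrix(0, n, spec$n_classes)
  Y[cbind(seq_len(n), train$labels + 1L)] <- 1
  rng <- local_rng(params$seed)
  p <- model$params %||% init_params(spec, rng$child_seed())
  dropout <- if (spec$family == "ffnn")
    max(params$dropout_rate, spec$dropout_rate) else 0
  losses <- numeric(params$epochs)
  lr <- params$learning_rate

  for (epoch in seq_len(params$epochs)) {
    idx <- rng$sample_int(n)
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = params$batch_size)) {
      b <- idx[start:min(start + params$batch_size - 1L, n)]
      Xb <- X[b, , drop = FALSE]; Yb <- Y[b, , drop = FALSE]
      m <- length(b)
      grad <- switch(spec$family,
        ffnn = {
          Z1 <- Xb %*% p$W1 + matrix(p$b1, m, length(p$b1), byrow = TRUE)
          A1 <- activation(spec$activation, Z1)
          if (dropout > 0) {
            M1 <- matrix(rng$rbinom(length(A1), 1L, 1 - dropout),
                         nrow(A1), ncol(A1)) / (1 - dropout)
            A1 <- A1 * M1
          }
          if (!is.null(p$W2)) {
            Z2 <- A1 %*% p$W2 + matrix(p$b2, m, length(p$b2), byrow = TRUE)
            A2 <- activation(spec$activation, Z2)
            if (dropout > 0) {
              M2 <- matrix(rng$rbinom(length(A2), 1L, 1 - dropout),
                           nrow(A2), ncol(A2)) / (1 - dropout)
              A2 <- A2 * M2
            }
          } else A2 <- A1
          P <- softmax_rows(A2 %*% p$Wo +
                              matrix(p$bo, m, length(p$bo), byrow = TRUE))
          loss <- cross_entropy(P, Yb)
          dZ <- (P - Yb) / m
          g <- list(Wo = t(A2) %*% dZ, bo = colSums(dZ))
          dA2 <- dZ %*% t(p$Wo)
          if (!is.null(p$W2)) {
            if (dropout > 0) dA2 <- dA2 * M2
            dZ2 <- dA2 * activation_grad(spec$activation, Z2)
            g$W2 <- t(A1) %*% dZ2; g$b2 <- colSums(dZ2)
            dA1 <- dZ2 %*% t(p$W2)
          } else dA1 <- dA2
          if (dropout > 0) dA1 <- dA1 * M1
          dZ1 <- dA1 * activation_grad(spec$activation, Z1)
          g$W1 <- t(Xb) %*% dZ1; g$b1 <- colSums(dZ1)
          list(loss = loss, g = g)
        },
        cnn = {
          fw <- cnn_flat(spec, p, Xb)
          P <- softmax_rows(fw$flat %*% p$Wo +
                              matrix(p$bo, m, length(p$bo), byrow = TRUE))
          loss <- cross_entropy(P, Yb)
          dZ <- (P - Yb) / m
          g <- list(Wo = t(fw$flat) %*% dZ, bo = colSums(dZ))
          dFlat <- dZ %*% t(p$Wo)
          dA <- matrix(array(dFlat, c(m, fw$L, spec$n_filters)),
                       m * fw$L, spec$n_filters)
          dCO <- dA * activation_grad(spec$activation, fw$CO)
          g$F <- t(dCO) %*% fw$XS
          g$bf <- colSums(dCO)
          list(loss = loss, g = g)
        },
        rnn = {
          fw <- gru_forward(spec, p, Xb, keep = TRUE)
          AH <- activation(spec$activation, fw$h)
          P <- softmax_rows(AH %*% p$Wo +
                              matrix(p$bo, m, length(p$bo), byrow = TRUE))
          loss <- cross_entropy(P, Yb)
          dZ <- (P - Yb) / m
          g <- list(Wo = t(AH) %*% dZ, bo = colSums(dZ))
          dh <- (dZ %*% t(p$Wo)) * activation_grad(spec$activation, fw$h)
          H <- spec$gru_units
          for (nm in c("W_r", "W_z", "W_h"))
            g[[nm]] <- matrix(0, H, 1L)
          for (nm in c("U_r", "U_z", "U_h")) g[[nm]] <- matrix(0, H, H)
          for (nm in c("b_r", "b_z", "b_h")) g[[nm]] <- numeric(H)
          for (t in rev(seq_len(ncol(Xb)))) {
            st <- fw$store[[t]]
            xt <- Xb[, t]
            dz_g <- dh * (st$h_prev - st$hc)
            dhc <- dh * (1 - st$z)
            dh_prev <- dh * st$z
            da_h <- dhc * (1 - st$hc^2)
            g$W_h <- g$W_h + t(da_h) %*% matrix(xt, m, 1L)
            g$U_h <- g$U_h + t(da_h) %*% st$v
            dv <- da_h %*% p$U_h
            g$b_h <- g$b_h + colSums(dv)
            dr <- dv * st$h_prev
            dh_prev <- dh_prev + dv * st$r
            da_r <- dr * st$r * (1 - st$r)
            g$W_r <- g$W_r + t(da_r) %*% matrix(xt, m, 1L)
            g$U_r <- g$U_r + t(da_r) %*% st$h_prev
            g$b_r <- g$b_r + colSums(da_r)
            dh_prev <- dh_prev + da_r %*% p$U_r
            da_z <- dz_g * st$z * (1 - st$z)
            g$W_z <- g$W_z + t(da_z) %*% matrix(xt, m, 1L)
            g$U_z <- g$U_z + t(da_z) %*% st$h_prev
            g$b_z <- g$b_z + colSums(da_z)
            dh <- dh_prev + da_z %*% p$U_z
          }
          list(loss = loss, g = g)
        }
      )
      if (!is.finite(grad$loss))
        stop("non-finite training loss at epoch ", epoch,
             " (learning rate ", lr, ", family ", spec$family,
             "); try a smaller learning rate")
      for (nm in names(grad$g)) p[[nm]] <- p[[nm]] - lr * grad$g[[nm]]
      batch_losses <- c(batch_losses, grad$loss)
    }
    losses[epoch] <- mean(batch_losses)
  }

  model$params <- p
  model$history <- list(loss = losses)
  model$training_params <- params
  model
}

#' Predict classes or class probabilities
#'
#' @param object A trained `mi_network`.
#' @param newdata A numeric matrix or [feature_matrix()] with the model's
#'   input width.
#' @param type `"class"` (default) for integer labels, `"prob"` for the
#'   softmax probability matrix (rows sum to 1).
#' @param ... Unused.
#' @return Integer labels in `0..C-1`, or an `n x C` probability matrix.
#' @export
predict.mi_network <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (is.null(object$params)) stop("model is untrained; call train_model()")
  if (ncol(newdata) != object$spec$n_inputs)
    stop("feature width ", ncol(newdata), " does not match model input ",
         object$spec$n_inputs)
  P <- forward_probs(object$spec, object$params, newdata)
  if (type == "prob") P else max.col(P, ties.method = "first") - 1L
}
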