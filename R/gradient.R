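#' Configuration for the gradient-descent baseline trainers
#'
#' Hyperparameters of the stochastic gradient descent with momentum (SGDM)
#' and ADAM comparators. The experiment defaults are a constant learning
#' rate of `1e-3`, mini-batches of 10, and 6 epochs; the momentum and ADAM
#' moment-decay constants are the standard textbook values.
#'
#' @param learning_rate Constant step size, > 0.
#' @param momentum SGDM momentum coefficient in \[0, 1).
#' @param beta1,beta2 ADAM first/second-moment decay rates in (0, 1).
#' @param eps_adam ADAM denominator stabilizer.
#' @param batch_size Mini-batch size, >= 1.
#' @param epochs Number of passes over the training data, >= 0.
#' @param seed Integer seed for the per-epoch shuffles and weight
#'   initialization.
#' @return An object of class `"gradient_config"`.
#' @export
gradient_config <- function(learning_rate = 1e-3, momentum = 0.9,
                            beta1 = 0.9, beta2 = 0.999, eps_adam = 1e-8,
                            batch_size = 10L, epochs = 6L, seed = 1L) {
  stopifnot(learning_rate >= 0, momentum >= 0, momentum < 1,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, eps_adam > 0,
            batch_size >= 1, epochs >= 0)
  structure(
    list(learning_rate = learning_rate, momentum = momentum,
         beta1 = beta1, beta2 = beta2, eps_adam = eps_adam,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         seed = as.integer(seed)),
    class = "gradient_config"
  )
}

#' One SGDM update
#'
#' `velocity <- momentum * velocity + grad;
#'  params <- params - learning_rate * velocity`.
#'
#' @param params,grad,velocity Numeric vectors of equal length.
#' @param cfg A [gradient_config()].
#' @return List with updated `params` and `velocity`.
#' @export
sgdm_step <- function(params, grad, velocity, cfg) {
  if (length(grad) != length(params) || length(velocity) != length(params)) {
    stop("params, grad and velocity must have the same length")
  }
  velocity <- cfg$momentum * velocity + grad
  list(params = params - cfg$learning_rate * velocity, velocity = velocity)
}

#' One ADAM update
#'
#' Standard bias-corrected moment estimates:
#' `m <- beta1*m + (1-beta1)*grad`, `v <- beta2*v + (1-beta2)*grad^2`,
#' `params <- params - lr * (m/(1-beta1^k)) / (sqrt(v/(1-beta2^k)) + eps)`.
#'
#' @param params,grad Numeric vectors of equal length.
#' @param moments List with first moment `m`, second moment `v`, and step
#'   counter `k` (>= 1 for the update being applied). Use
#'   `list(m = 0*params, v = 0*params, k = 1L)` at the start.
#' @param cfg A [gradient_config()].
#' @return List with updated `params` and `moments` (with `k` advanced).
#' @export
adam_step <- function(params, grad, moments, cfg) {
  if (length(grad) != length(params)) {
    stop("params and grad must have the same length")
  }
  k <- moments$k
  stopifnot(k >= 1)
  m <- cfg$beta1 * moments$m + (1 - cfg$beta1) * grad
  v <- cfg$beta2 * moments$v + (1 - cfg$beta2) * grad^2
  mhat <- m / (1 - cfg$beta1^k)
  vhat <- v / (1 - cfg$beta2^k)
  params <- params - cfg$learning_rate * mhat / (sqrt(vhat) + cfg$eps_adam)
  list(params = params, moments = list(m = m, v = v, k = k + 1L))
}

#' Exact gradient of the batch loss by backpropagation
#'
#' Returns the analytic gradient of [nn_loss()] with respect to the
#' flattened weight vector, in the same layout as [flatten_weights()].
#'
#' @param spec A [network_spec()].
#' @param values Flattened parameter vector.
#' @param X,y Non-empty batch of features and 0/1 labels.
#' @param loss `"mse"` or `"ce"`, as in [nn_loss()].
#' @return Numeric gradient vector of length [parameter_count()].
#' @export
backprop_gradient <- function(spec, values, X, y, loss = c("mse", "ce")) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  N <- nrow(X)
  if (N == 0) stop("empty batch")
  stopifnot(length(y) == N)
  fw <- .forward_full(spec, values, X)
  p <- fw$p
  nl <- length(fw$layers)
  # delta at the output pre-activation
  delta <- if (loss == "mse") {
    matrix(2 * (p - y) * p * (1 - p) / N, ncol = 1)
  } else {
    matrix((p - y) / N, ncol = 1)
  }
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    gW <- crossprod(fw$A[[l]], delta)
    gb <- colSums(delta)
    grads[[l]] <- list(W = gW, b = gb)
    if (l > 1) {
      delta <- (delta %*% t(fw$layers[[l]]$W)) * (fw$Z[[l - 1]] > 0)
    }
  }
  flatten_weights(grads)
}

#' Train the network with a gradient-based optimizer
#'
#' Mini-batch training with seeded per-epoch shuffling. Weights are
#' initialized uniformly in \[-0.5, 0.5\] from the same seed, so a run is
#' fully reproducible.
#'
#' @param spec A [network_spec()].
#' @param X,y Preprocessed training data (features in \[0, 1\], labels 0/1).
#' @param cfg A [gradient_config()].
#' @param method `"sgdm"` or `"adam"`.
#' @param loss `"mse"` or `"ce"`.
#' @return List of class `"gmvo_model"` with `weights` and a `history` data
#'   frame (per-epoch training loss and accuracy).
#' @export
train_gradient <- function(spec, X, y, cfg = gradient_config(),
                           method = c("sgdm", "adam"),
                           loss = c("mse", "ce")) {
  method <- match.arg(method)
  loss <- match.arg(loss)
  X <- as.matrix(X)
  N <- nrow(X)
  P <- parameter_count(spec)
  set.seed(cfg$seed)
  params <- stats::runif(P, -0.5, 0.5)
  velocity <- numeric(P)
  moments <- list(m = numeric(P), v = numeric(P), k = 1L)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(N)
    starts <- seq(1, N, by = cfg$batch_size)
    for (s in starts) {
      b <- idx[s:min(s + cfg$batch_size - 1, N)]
      g <- backprop_gradient(spec, params, X[b, , drop = FALSE], y[b], loss)
      if (method == "sgdm") {
        upd <- sgdm_step(params, g, velocity, cfg)
        params <- upd$params; velocity <- upd$velocity
      } else {
        upd <- adam_step(params, g, moments, cfg)
        params <- upd$params; moments <- upd$moments
      }
    }
    history <- rbind(history, data.frame(
      epoch = ep,
      loss = nn_loss(spec, params, X, y, loss),
      accuracy = mean(nn_predict(spec, params, X) == y)))
  }
  structure(
    list(spec = spec, weights = params,
         best_fitness = if (nrow(history)) history$loss[nrow(history)]
                        else nn_loss(spec, params, X, y, loss),
         history = history, config = cfg, loss = loss, method = method),
    class = "gmvo_model"
  )
}
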