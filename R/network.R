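#' Specify the feed-forward classifier architecture
#'
#' A fixed-depth multilayer perceptron with exactly three hidden layers,
#' ReLU activations on the hidden layers, and a single sigmoid output node
#' for binary diagnosis. The two stock architectures are `c(5, 3, 2)` hidden
#' nodes for the 9-feature ordinal dataset and `c(8, 4, 2)` for the
#' 17-feature continuous dataset.
#'
#' @param d_in Number of input features (>= 1).
#' @param hidden Integer vector of exactly three hidden-layer sizes, all
#'   >= 1.
#' @return An object of class `"network_spec"` with `layer_sizes`
#'   `c(d_in, hidden, 1)`.
#' @export
#' @examples
#' network_spec(9)           # 9-5-3-2-1
#' network_spec(17, c(8, 4, 2))
network_spec <- function(d_in, hidden = c(5, 3, 2)) {
  stopifnot(length(hidden) == 3, all(hidden >= 1), d_in >= 1)
  structure(
    list(layer_sizes = as.integer(c(d_in, hidden, 1L))),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat("feed-forward network:", paste(x$layer_sizes, collapse = "-"),
      "(ReLU hidden, sigmoid output)\n")
  invisible(x)
}

#' Number of trainable parameters of a network
#'
#' Sums `in_l * out_l + out_l` over the four weight layers; this is the
#' dimension of the flattened weight vector the population optimizer
#' searches.
#'
#' @param spec A [network_spec()].
#' @return Integer parameter count.
#' @export
#' @examples
#' parameter_count(network_spec(9))  # 79
#' parameter_count(network_spec(17, c(8, 4, 2)))  # 193
parameter_count <- function(spec) {
  ls <- spec$layer_sizes
  nl <- length(ls)
  sum(ls[-nl] * ls[-1] + ls[-1])
}

# Deterministic flat layout: per layer, the in x out weight matrix stored
# row-major (all outgoing weights of input unit 1, then unit 2, ...),
# followed by the out biases.
#' Unflatten a parameter vector into per-layer weights and biases
#'
#' @param spec A [network_spec()].
#' @param values Numeric vector of length [parameter_count()].
#' @return List with one element per layer, each `list(W, b)` where `W` is
#'   `in x out`.
#' @export
unflatten_weights <- function(spec, values) {
  ls <- spec$layer_sizes
  P <- parameter_count(spec)
  if (length(values) != P) {
    stop(sprintf("expected %d parameters, got %d", P, length(values)))
  }
  layers <- vector("list", length(ls) - 1)
  off <- 0L
  for (l in seq_along(layers)) {
    din <- ls[l]; dout <- ls[l + 1]
    W <- matrix(values[off + seq_len(din * dout)], nrow = din, ncol = dout,
                byrow = TRUE)
    off <- off + din * dout
    b <- values[off + seq_len(dout)]
    off <- off + dout
    layers[[l]] <- list(W = W, b = b)
  }
  layers
}

#' Flatten per-layer weights into a single parameter vector
#'
#' Inverse of [unflatten_weights()]: `flatten_weights(unflatten_weights(s, v))`
#' recovers `v` exactly.
#'
#' @param layers List of `list(W, b)` per layer as returned by
#'   [unflatten_weights()].
#' @return Numeric parameter vector.
#' @export
flatten_weights <- function(layers) {
  unlist(lapply(layers, function(l) c(as.vector(t(l$W)), l$b)),
         use.names = FALSE)
}

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass keeping intermediate activations (for backpropagation).
.forward_full <- function(spec, values, X) {
  layers <- unflatten_weights(spec, values)
  A <- list(as.matrix(X))
  Z <- vector("list", length(layers))
  nl <- length(layers)
  for (l in seq_len(nl)) {
    Z[[l]] <- sweep(A[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    A[[l + 1]] <- if (l < nl) relu(Z[[l]]) else sigmoid(Z[[l]])
  }
  list(layers = layers, A = A, Z = Z, p = as.vector(A[[nl + 1]]))
}

#' Forward pass: class-1 probabilities
#'
#' @param spec A [network_spec()].
#' @param values Flattened parameter vector.
#' @param X Numeric matrix, samples in rows, `d_in` columns.
#' @return Numeric vector of probabilities in (0, 1), one per row of `X`.
#' @export
#' @examples
#' sp <- network_spec(2, c(1, 1, 1))
#' nn_forward(sp, numeric(parameter_count(sp)), matrix(0, 1, 2)) # 0.5
nn_forward <- function(spec, values, X) {
  X <- as.matrix(X)
  if (ncol(X) != spec$layer_sizes[1]) {
    stop(sprintf("X has %d columns but the network expects %d features",
                 ncol(X), spec$layer_sizes[1]))
  }
  .forward_full(spec, values, X)$p
}

#' Training loss of a weight vector
#'
#' The objective minimized when the network is trained by a population
#' optimizer: mean squared error between the output probabilities and the
#' 0/1 labels (the default), or mean binary cross-entropy.
#'
#' @inheritParams nn_forward
#' @param y Binary label vector (0 = benign, 1 = malignant).
#' @param loss Either `"mse"` (default) or `"ce"`.
#' @return Non-negative scalar loss.
#' @export
nn_loss <- function(spec, values, X, y, loss = c("mse", "ce")) {
  loss <- match.arg(loss)
  if (length(y) == 0) stop("empty data")
  stopifnot(length(y) == nrow(as.matrix(X)), all(y %in% c(0, 1)))
  p <- nn_forward(spec, values, X)
  if (loss == "mse") {
    mean((p - y)^2)
  } else {
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(pc) + (1 - y) * log(1 - pc))
  }
}

#' Predict binary labels
#'
#' A probability at or above the threshold is labelled 1 (malignant); the
#' tie at exactly the threshold goes to the positive class.
#'
#' @inheritParams nn_forward
#' @param threshold Decision threshold in \[0, 1\], default 0.5.
#' @return Integer vector of 0/1 labels.
#' @export
nn_predict <- function(spec, values, X, threshold = 0.5) {
  as.integer(nn_forward(spec, values, X) >= threshold)
}

#' Train the network by population search over its flattened weights
#'
#' Wraps the full-training-set loss as the black-box objective of
#' [optimize_mvo()]: each universe is one candidate weight vector, and the
#' returned model carries the best universe found. The search box defaults
#' to \[-10, 10\] per coordinate.
#'
#' @param spec A [network_spec()].
#' @param X,y Training features (rows = samples) and 0/1 labels.
#' @param cfg An [mvo_config()] whose dimension, if it disagrees with
#'   [parameter_count()], is re-derived from the network (bounds are
#'   recycled).
#' @param loss Loss passed to [nn_loss()].
#' @return List of class `"gmvo_model"`: `spec`, `weights` (flattened best
#'   vector), `history`, `best_fitness`, `config`.
#' @export
train_population <- function(spec, X, y, cfg = mvo_config(d = parameter_count(spec)),
                             loss = c("mse", "ce")) {
  loss <- match.arg(loss)
  P <- parameter_count(spec)
  if (cfg$d != P) {
    cfg <- mvo_config(lb = cfg$lb[1], ub = cfg$ub[1], d = P, n = cfg$n,
                      M = cfg$M, P_min = cfg$P_min, P_max = cfg$P_max,
                      chi = cfg$chi, alpha = cfg$alpha,
                      delta_x_interval = cfg$delta_x_interval,
                      eps = cfg$eps, s_max = cfg$s_max, seed = cfg$seed)
  }
  X <- as.matrix(X)
  objective <- function(w) nn_loss(spec, w, X, y, loss)
  res <- optimize_mvo(objective, cfg)
  structure(
    list(spec = spec, weights = res$best_position,
         best_fitness = res$best_fitness, history = res$history,
         config = cfg, loss = loss),
    class = "gmvo_model"
  )
}

#' @export
print.gmvo_model <- function(x, ...) {
  cat("population-trained network",
      paste(x$spec$layer_sizes, collapse = "-"), "\n")
  cat(sprintf("  final training %s: %.6g\n", x$loss, x$best_fitness))
  invisible(x)
}

#' Serialize a trained model to JSON
#'
#' Stores the architecture, flattened weights, optional preprocessing
#' statistics (per-feature min/max), and the training configuration, so a
#' model can be re-loaded and applied without re-training.
#'
#' @param model A `"gmvo_model"` from [train_population()].
#' @param path File path to write.
#' @param ranges Optional data frame of per-feature `min`/`max` from
#'   [minmax_fit_apply()].
#' @return `path`, invisibly.
#' @export
save_model_json <- function(model, path, ranges = NULL) {
  obj <- list(
    layer_sizes = model$spec$layer_sizes,
    weights = model$weights,
    loss = model$loss,
    seed = model$config$seed,
    config = model$config[c("n", "M", "P_min", "P_max", "chi", "alpha", "eps")],
    ranges = ranges
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model_json()]
#'
#' @param path File written by [save_model_json()].
#' @return A list with `spec`, `weights`, and `ranges` ready for
#'   [nn_predict()].
#' @export
load_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ls <- obj$layer_sizes
  spec <- network_spec(ls[1], ls[2:4])
  list(spec = spec, weights = as.numeric(obj$weights), ranges = obj$ranges,
       loss = obj$loss)
}
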