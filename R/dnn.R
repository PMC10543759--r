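#' Build the pair-classification deep neural network
#'
#' Feed-forward network over concatenated pair embeddings: input width `a`
#' (128 under the 64+64 embedding defaults), hidden layers of 100, 100 and
#' 50 ReLU units, and a single sigmoid output unit giving the association
#' probability. Weights use seeded He-style initialization.
#'
#' @param layer_sizes integer vector of layer widths including input and
#'   the final single unit (default `c(128, 100, 100, 50, 1)`).
#' @param dropout dropout rate applied after each hidden layer during
#'   training (default 0.2).
#' @param learning_rate Adam step size (default 0.001).
#' @param seed RNG seed for initialization.
#' @return object of class `dnn_model`.
#' @export
build_dnn <- function(layer_sizes = c(128L, 100L, 100L, 50L, 1L),
                      dropout = 0.2, learning_rate = 0.001, seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (any(layer_sizes <= 0L)) stop("layer sizes must be positive")
  if (length(layer_sizes) < 2L) stop("need at least input and output layers")
  if (utils::tail(layer_sizes, 1L) != 1L) stop("output layer must have one unit")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  L <- length(layer_sizes) - 1L
  with_seed(seed, {
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- layer_sizes[l]
      W[[l]] <- matrix(stats::rnorm(fan_in * layer_sizes[l + 1L], 0, sqrt(2 / fan_in)),
                       fan_in, layer_sizes[l + 1L])
      b[[l]] <- numeric(layer_sizes[l + 1L])
    }
    structure(
      list(W = W, b = b, layer_sizes = layer_sizes, dropout = dropout,
           learning_rate = learning_rate, seed = as.integer(seed)),
      class = "dnn_model"
    )
  })
}

#' @export
print.dnn_model <- function(x, ...) {
  n_par <- sum(vapply(x$W, length, 1) + vapply(x$b, length, 1))
  cat(sprintf(
    "<dnn_model> %s (%d parameters), dropout %.2f\n",
    paste(x$layer_sizes, collapse = " -> "), n_par, x$dropout
  ))
  invisible(x)
}

#' Number of trainable parameters in a DNN
#' @param model a `dnn_model`.
#' @return integer parameter count (weights plus biases).
#' @export
dnn_n_params <- function(model) {
  sum(vapply(model$W, length, 1) + vapply(model$b, length, 1))
}

# Forward pass; when `masks` is given (training), inverted dropout is
# applied after each hidden ReLU. Returns activations for backprop.
dnn_forward <- function(model, X, masks = NULL) {
  L <- length(model$W)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% model$W[[l]], 2L, model$b[[l]], "+")
    if (l < L) {
      h <- pmax(Z[[l]], 0)
      if (!is.null(masks)) h <- h * masks[[l]]
      A[[l + 1L]] <- h
    } else {
      A[[l + 1L]] <- sigmoid(Z[[l]])
    }
  }
  list(A = A, Z = Z)
}

#' Train the DNN on labeled pairs
#'
#' Minimizes binary cross-entropy with mini-batch Adam. Both classes must
#' be present. Deterministic for a fixed seed (seed drives initialization,
#' batch shuffling and dropout masks).
#'
#' @param model a [build_dnn()] model.
#' @param X feature matrix (`n x a`, `a` matching the model input width).
#' @param y 0/1 label vector.
#' @param epochs training epochs (default 300; larger corpora warrant more,
#'   e.g. 1500 at Disbiome scale).
#' @param batch_size mini-batch size (default 32).
#' @param seed RNG seed.
#' @return list with `model` (trained) and `loss_trace` (mean per-epoch
#'   binary cross-entropy).
#' @export
train_dnn <- function(model, X, y, epochs = 300L, batch_size = 32L, seed = 1L) {
  stopifnot(inherits(model, "dnn_model"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (ncol(X) != model$layer_sizes[1L]) {
    stop(sprintf("feature width %d does not match model input width %d",
                 ncol(X), model$layer_sizes[1L]))
  }
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  n <- nrow(X)
  L <- length(model$W)
  params <- c(model$W, model$b)
  st <- adam_state(params)
  lr <- model$learning_rate
  p_drop <- model$dropout
  trace <- numeric(epochs)
  t_step <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        idx <- perm[s:min(s + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        masks <- NULL
        if (p_drop > 0) {
          masks <- lapply(seq_len(L - 1L), function(l) {
            matrix(
              (stats::runif(length(idx) * model$layer_sizes[l + 1L]) >= p_drop) / (1 - p_drop),
              length(idx), model$layer_sizes[l + 1L]
            )
          })
        }
        fw <- dnn_forward(model, Xb, masks)
        p <- fw$A[[L + 1L]][, 1L]
        p_cl <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        ep_loss <- ep_loss - sum(yb * log(p_cl) + (1 - yb) * log(1 - p_cl))
        # BCE + sigmoid: dL/dz = (p - y) / batch
        delta <- matrix((p - yb) / length(idx), ncol = 1L)
        t_step <- t_step + 1L
        for (l in rev(seq_len(L))) {
          gW <- crossprod(fw$A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(model$W[[l]])
            delta <- delta * (fw$Z[[l - 1L]] > 0)
            if (!is.null(masks)) delta <- delta * masks[[l - 1L]]
          }
          upW <- adam_update(model$W[[l]], gW, st[[l]], lr, t_step)
          model$W[[l]] <- upW$p; st[[l]] <- upW$st
          upb <- adam_update(model$b[[l]], gb, st[[L + l]], lr, t_step)
          model$b[[l]] <- upb$p; st[[L + l]] <- upb$st
        }
      }
      trace[ep] <- ep_loss / n
      if (!is.finite(trace[ep])) stop(sprintf("training diverged at epoch %d", ep))
    }
  })
  list(model = model, loss_trace = trace)
}

#' Predict association scores for pairs
#'
#' Forward pass with dropout disabled; scores are sigmoid outputs clamped
#' strictly inside `(0, 1)`.
#'
#' @param model a trained `dnn_model`.
#' @param X feature matrix or a `pair_dataset`.
#' @return numeric score vector.
#' @export
predict_scores <- function(model, X) {
  if (inherits(X, "pair_dataset")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) != model$layer_sizes[1L]) {
    stop(sprintf("feature width %d does not match model input width %d",
                 ncol(X), model$layer_sizes[1L]))
  }
  p <- dnn_forward(model, X)$A[[length(model$W) + 1L]][, 1L]
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}
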