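#' Build a k-nearest-neighbor attributed graph from a similarity matrix
#'
#' Sparsifies a dense fused similarity matrix into neighbor sets: each node
#' keeps itself plus its `k_neighbors` most similar other nodes (ties broken
#' toward the lower index), and carries a node-attribute row consumed by the
#' autoencoder. By default downstream code uses the node's association
#' profile as its attribute row.
#'
#' @param similarity a [similarity_matrix] (normally kind `"fused"`).
#' @param attributes numeric matrix, one row per node, aligned with
#'   `similarity$names`.
#' @param k_neighbors number of neighbors per node (excluding self);
#'   must be smaller than the node count.
#' @return An object of class `attributed_graph`: neighbor sets, a sorted
#'   directed edge list (`ei`, `ej`, `j` in `N_i`, self-loops included),
#'   and the attribute matrix `X`.
#' @export
build_graph <- function(similarity, attributes, k_neighbors = 10L) {
  stopifnot(inherits(similarity, "similarity_matrix"))
  S <- similarity$S
  n <- nrow(S)
  attributes <- as.matrix(attributes)
  if (nrow(attributes) != n) stop("attribute rows must match node count")
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the node count")
  if (k_neighbors < 0L) stop("k_neighbors must be nonnegative")
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    cand <- setdiff(order(-s, seq_len(n)), i)  # ties -> lower index first
    neighbors[[i]] <- sort(unique(c(i, cand[seq_len(k_neighbors)])))
  }
  ei <- rep.int(seq_len(n), lengths(neighbors))
  ej <- unlist(neighbors, use.names = FALSE)
  structure(
    list(
      neighbors = neighbors, ei = ei, ej = ej,
      X = attributes, names = similarity$names, n = n
    ),
    class = "attributed_graph"
  )
}

#' @export
print.attributed_graph <- function(x, ...) {
  cat(sprintf(
    "<attributed_graph> %d nodes, %d directed edges (self-loops included), %d attributes/node\n",
    x$n, length(x$ei), ncol(x$X)
  ))
  invisible(x)
}

glorot_mat <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

new_gate_layer <- function(d_in, d_out) {
  list(W = glorot_mat(d_in, d_out), vs = stats::runif(d_out, -0.1, 0.1),
       vr = stats::runif(d_out, -0.1, 0.1))
}

#' Initialize a graph attention autoencoder
#'
#' Builds encoder layers mapping the attribute dimension down to the
#' embedding dimension and a mirrored decoder mapping back. Each layer owns
#' a transform matrix `W` and two attention vectors (`vs` for the source
#' node, `vr` for the neighbor); attention logits pass through a sigmoid
#' and are softmax-normalized over each neighbor set. Transforms use tanh;
#' initialization is uniform Glorot, seeded for reproducibility.
#'
#' @param attr_dim width of the node attribute rows.
#' @param embedding_dim embedding width (default 64).
#' @param hidden_dims optional integer vector of intermediate encoder
#'   widths for deeper models (decoder mirrors them).
#' @param lambda nonnegative weight of the graph-structure reconstruction
#'   term in the loss (default 1).
#' @param seed RNG seed for weight initialization.
#' @return An object of class `gate_model`.
#' @export
gate_init <- function(attr_dim, embedding_dim = 64L, hidden_dims = NULL,
                      lambda = 1, seed = 1L) {
  if (lambda < 0) stop("lambda must be nonnegative")
  dims <- c(attr_dim, hidden_dims, embedding_dim)
  with_seed(seed, {
    enc <- lapply(seq_len(length(dims) - 1L), function(k) {
      new_gate_layer(dims[k], dims[k + 1L])
    })
    dec <- lapply(rev(seq_len(length(dims) - 1L)), function(k) {
      new_gate_layer(dims[k + 1L], dims[k])
    })
    structure(
      list(encoder = enc, decoder = dec, dims = dims, lambda = lambda,
           seed = as.integer(seed)),
      class = "gate_model"
    )
  })
}

#' @export
print.gate_model <- function(x, ...) {
  cat(sprintf(
    "<gate_model> encoder %s, lambda = %g\n",
    paste(x$dims, collapse = " -> "), x$lambda
  ))
  invisible(x)
}

# One attention layer, shared by encoder and decoder:
#   S    = tanh(Hin W)
#   c_ij = sigmoid(vs' S_i + vr' S_j)          (attention logit)
#   a_ij = softmax over j in N_i of c_ij
#   Hout_i = sum_j a_ij S_j
gate_layer_forward <- function(Hin, layer, graph) {
  ei <- graph$ei; ej <- graph$ej
  S <- tanh(Hin %*% layer$W)
  u <- as.vector(S %*% layer$vs)
  r <- as.vector(S %*% layer$vr)
  cc <- sigmoid(u[ei] + r[ej])
  e <- exp(cc)  # cc in (0,1): no overflow possible
  denom <- rowsum(e, ei)[, 1L]
  alpha <- unname(e / denom[ei])
  Hout <- rowsum(alpha * S[ej, , drop = FALSE], ei)
  dimnames(Hout) <- NULL
  list(Hin = Hin, S = S, cc = cc, alpha = alpha, Hout = Hout)
}

# Backward pass for one attention layer. Gout = dLoss/dHout.
# Returns gradient w.r.t. Hin plus parameter gradients.
gate_layer_backward <- function(cache, layer, graph, Gout) {
  ei <- graph$ei; ej <- graph$ej
  S <- cache$S; alpha <- cache$alpha; cc <- cache$cc
  d_alpha <- rowSums(Gout[ei, , drop = FALSE] * S[ej, , drop = FALSE])
  dS <- rowsum(alpha * Gout[ei, , drop = FALSE], ej)
  # softmax backward within each neighbor set
  srow <- rowsum(alpha * d_alpha, ei)[, 1L]
  d_c <- alpha * (d_alpha - srow[ei])
  g <- cc * (1 - cc) * d_c
  du <- rowsum(g, ei)[, 1L]
  dr <- rowsum(g, ej)[, 1L]
  dS <- dS + outer(du, layer$vs) + outer(dr, layer$vr)
  d_vs <- as.vector(crossprod(S, du))
  d_vr <- as.vector(crossprod(S, dr))
  dZ <- dS * (1 - S^2)
  list(
    dHin = dZ %*% t(layer$W),
    dW = crossprod(cache$Hin, dZ),
    dvs = d_vs, dvr = d_vr
  )
}

#' Encode node attributes into embeddings
#'
#' Runs the encoder stack: each layer aggregates tanh-transformed neighbor
#' representations with softmax-normalized attention weights. The final
#' layer's rows are the node embeddings.
#'
#' @param model a [gate_init()] model.
#' @param graph an [build_graph()] attributed graph.
#' @return list with `layers` (per-layer caches), and `embedding`, an
#'   `embedding_set` (names + matrix `H`).
#' @export
gate_encode <- function(model, graph) {
  H <- graph$X
  caches <- vector("list", length(model$encoder))
  for (k in seq_along(model$encoder)) {
    caches[[k]] <- gate_layer_forward(H, model$encoder[[k]], graph)
    H <- caches[[k]]$Hout
    if (!all(is.finite(H))) stop(sprintf("non-finite values in encoder layer %d", k))
  }
  emb <- structure(list(names = graph$names, H = H), class = "embedding_set")
  list(layers = caches, embedding = emb)
}

#' Decode embeddings back to node attributes
#'
#' Mirrors the encoder: attention-weighted aggregation through the decoder
#' stack reconstructs the attribute matrix.
#'
#' @param model a [gate_init()] model.
#' @param embedding an `embedding_set` from [gate_encode()] (or its `H`).
#' @param graph the same attributed graph used for encoding.
#' @return list with `layers` (per-layer caches) and `Xhat`, the
#'   reconstructed attribute matrix.
#' @export
gate_decode <- function(model, embedding, graph) {
  H <- if (inherits(embedding, "embedding_set")) embedding$H else as.matrix(embedding)
  caches <- vector("list", length(model$decoder))
  for (k in seq_along(model$decoder)) {
    caches[[k]] <- gate_layer_forward(H, model$decoder[[k]], graph)
    H <- caches[[k]]$Hout
    if (!all(is.finite(H))) stop(sprintf("non-finite values in decoder layer %d", k))
  }
  list(layers = caches, Xhat = H)
}

#' Attention weights of one autoencoder layer
#'
#' Exposes the softmax-normalized attention coefficients `a_ij` over each
#' node's neighbor set for a given layer, computed from the supplied input
#' representations. Each node's weights are positive and sum to one.
#'
#' @param model a [gate_init()] model.
#' @param graph the attributed graph.
#' @param H input representations for the layer (`n x d_in`).
#' @param layer layer index (default 1).
#' @param direction `"encode"` or `"decode"`.
#' @return tibble with columns `i`, `j`, `alpha`.
#' @export
attention_weights <- function(model, graph, H, layer = 1L,
                              direction = c("encode", "decode")) {
  direction <- match.arg(direction)
  params <- if (direction == "encode") model$encoder[[layer]] else model$decoder[[layer]]
  fw <- gate_layer_forward(as.matrix(H), params, graph)
  tibble::tibble(i = graph$ei, j = graph$ej, alpha = fw$alpha)
}

#' Autoencoder loss
#'
#' `Loss = sum_i ||x_i - xhat_i||^2 - lambda * sum_{(i,j) in E} log sigmoid(h_i' h_j)`:
#' squared attribute-reconstruction error plus a graph-structure term that
#' rewards large inner products between embeddings of neighboring nodes.
#'
#' @param graph the attributed graph (provides `X` and the edge list).
#' @param embedding embeddings (`embedding_set` or matrix).
#' @param Xhat reconstructed attributes.
#' @param lambda nonnegative structure weight.
#' @return scalar loss.
#' @export
gate_loss <- function(graph, embedding, Xhat, lambda = 1) {
  if (lambda < 0) stop("lambda must be nonnegative")
  H <- if (inherits(embedding, "embedding_set")) embedding$H else as.matrix(embedding)
  recon <- sum((graph$X - Xhat)^2)
  dots <- rowSums(H[graph$ei, , drop = FALSE] * H[graph$ej, , drop = FALSE])
  recon - lambda * sum(log_sigmoid(dots))
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

flatten_gate <- function(model) {
  out <- list()
  for (k in seq_along(model$encoder)) {
    for (nm in c("W", "vs", "vr")) out[[paste0("e", k, ".", nm)]] <- model$encoder[[k]][[nm]]
  }
  for (k in seq_along(model$decoder)) {
    for (nm in c("W", "vs", "vr")) out[[paste0("d", k, ".", nm)]] <- model$decoder[[k]][[nm]]
  }
  out
}

unflatten_gate <- function(model, flat) {
  for (k in seq_along(model$encoder)) {
    for (nm in c("W", "vs", "vr")) model$encoder[[k]][[nm]] <- flat[[paste0("e", k, ".", nm)]]
  }
  for (k in seq_along(model$decoder)) {
    for (nm in c("W", "vs", "vr")) model$decoder[[k]][[nm]] <- flat[[paste0("d", k, ".", nm)]]
  }
  model
}

# Full-batch loss and analytic gradients for every parameter.
gate_loss_grads <- function(model, graph) {
  enc <- gate_encode(model, graph)
  H <- enc$embedding$H
  dec <- gate_decode(model, H, graph)
  Xhat <- dec$Xhat
  loss <- gate_loss(graph, H, Xhat, model$lambda)
  ei <- graph$ei; ej <- graph$ej
  grads <- list()
  # reconstruction term through the decoder
  G <- 2 * (Xhat - graph$X)
  for (k in rev(seq_along(model$decoder))) {
    bk <- gate_layer_backward(dec$layers[[k]], model$decoder[[k]], graph, G)
    grads[[paste0("d", k, ".W")]] <- bk$dW
    grads[[paste0("d", k, ".vs")]] <- bk$dvs
    grads[[paste0("d", k, ".vr")]] <- bk$dvr
    G <- bk$dHin
  }
  # structure term gradient acts directly on the embeddings
  dots <- rowSums(H[ei, , drop = FALSE] * H[ej, , drop = FALSE])
  w <- -model$lambda * (1 - sigmoid(dots))
  G <- G + rowsum(w * H[ej, , drop = FALSE], ei) + rowsum(w * H[ei, , drop = FALSE], ej)
  for (k in rev(seq_along(model$encoder))) {
    bk <- gate_layer_backward(enc$layers[[k]], model$encoder[[k]], graph, G)
    grads[[paste0("e", k, ".W")]] <- bk$dW
    grads[[paste0("e", k, ".vs")]] <- bk$dvs
    grads[[paste0("e", k, ".vr")]] <- bk$dvr
    G <- bk$dHin
  }
  list(loss = loss, grads = grads, embedding = enc$embedding, Xhat = Xhat)
}

#' Train the graph attention autoencoder
#'
#' Full-batch Adam on the autoencoder loss. Deterministic for a fixed seed
#' (seed controls weight initialization; the optimization itself has no
#' randomness).
#'
#' @param graph an attributed graph from [build_graph()].
#' @param embedding_dim embedding width (default 64).
#' @param epochs training epochs (default 200).
#' @param learning_rate Adam step size (default 0.001).
#' @param lambda structure-loss weight (default 1).
#' @param hidden_dims optional deeper encoder widths.
#' @param seed RNG seed.
#' @return list with `model` (trained `gate_model`), `embedding`
#'   (`embedding_set`), and `loss_trace` (per-epoch loss, epoch 0 =
#'   untrained).
#' @export
train_gate <- function(graph, embedding_dim = 64L, epochs = 200L,
                       learning_rate = 0.001, lambda = 1,
                       hidden_dims = NULL, seed = 1L) {
  model <- gate_init(ncol(graph$X), embedding_dim, hidden_dims, lambda, seed)
  flat <- flatten_gate(model)
  st <- adam_state(flat)
  trace <- numeric(epochs + 1L)
  lg <- gate_loss_grads(model, graph)
  trace[1L] <- lg$loss
  for (ep in seq_len(epochs)) {
    for (nm in names(flat)) {
      up <- adam_update(flat[[nm]], lg$grads[[nm]], st[[nm]], learning_rate, ep)
      flat[[nm]] <- up$p
      st[[nm]] <- up$st
    }
    model <- unflatten_gate(model, flat)
    lg <- gate_loss_grads(model, graph)
    if (!is.finite(lg$loss)) stop(sprintf("training diverged at epoch %d", ep))
    trace[ep + 1L] <- lg$loss
  }
  list(model = model, embedding = lg$embedding, loss_trace = trace)
}

#' Concatenated microbe + disease pair features
#'
#' Builds the classifier's feature rows: for each (disease, microbe) pair,
#' the microbe embedding followed by the disease embedding, giving width
#' `d_microbe + d_disease` (128 under the 64-dimensional defaults).
#'
#' @param microbe_emb `embedding_set` for microbes.
#' @param disease_emb `embedding_set` for diseases.
#' @param pairs two-column matrix or data frame of (disease index,
#'   microbe index).
#' @param label optional per-pair labels: 1 (known association), 0
#'   (assigned negative) or `NA` (unlabeled).
#' @return An object of class `pair_dataset`: tibble `pairs` (indices and
#'   names), feature matrix `X`, and `label` vector.
#' @export
make_pair_features <- function(microbe_emb, disease_emb, pairs, label = NULL) {
  stopifnot(inherits(microbe_emb, "embedding_set"), inherits(disease_emb, "embedding_set"))
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  di <- as.integer(pairs[, 1L]); mi <- as.integer(pairs[, 2L])
  if (any(di < 1L | di > nrow(disease_emb$H))) stop("unknown disease index in pairs")
  if (any(mi < 1L | mi > nrow(microbe_emb$H))) stop("unknown microbe index in pairs")
  X <- cbind(microbe_emb$H[mi, , drop = FALSE], disease_emb$H[di, , drop = FALSE])
  rownames(X) <- NULL
  if (is.null(label)) label <- rep(NA_real_, nrow(X))
  stopifnot(length(label) == nrow(X))
  structure(
    list(
      pairs = tibble::tibble(
        disease = di, microbe = mi,
        disease_name = disease_emb$names[di], microbe_name = microbe_emb$names[mi]
      ),
      X = X, label = as.numeric(label)
    ),
    class = "pair_dataset"
  )
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf(
    "<pair_dataset> %d pairs, %d features; %d positive / %d negative / %d unlabeled\n",
    nrow(x$X), ncol(x$X), sum(x$label == 1, na.rm = TRUE),
    sum(x$label == 0, na.rm = TRUE), sum(is.na(x$label))
  ))
  invisible(x)
}
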