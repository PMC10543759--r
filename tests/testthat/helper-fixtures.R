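# Shared fixtures built in code at test time.

# Random binary association matrix with at least one 1.
random_binary_Y <- function(n, m, p = 0.3) {
  Y <- matrix(as.numeric(rbinom(n * m, 1, p)), n, m)
  if (sum(Y) == 0) Y[sample(length(Y), 1)] <- 1
  dimnames(Y) <- list(paste0("d", seq_len(n)), paste0("m", seq_len(m)))
  Y
}

# Scalar-loop kernel-similarity oracle: per-pair evaluation of
# exp(-theta * ||Vi - Vj||^2) with theta = n / sum ||Vi||^2.
oracle_gapk <- function(Y, side) {
  P <- if (side == "disease") Y else t(Y)
  theta <- nrow(P) / sum(P^2)
  n <- nrow(P)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      G[i, j] <- exp(-theta * sum((P[i, ] - P[j, ])^2))
    }
  }
  G
}

# O(n^2) pairwise Mann-Whitney AUC oracle with ties counted half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Small attributed graph on a random association matrix.
small_graph <- function(n = 5, m = 6, k = 2, seed = 1) {
  set.seed(seed)
  Y <- random_binary_Y(n, m, 0.4)
  S <- side_similarity(Y, "disease")
  build_graph(S, Y, k)
}

# Nested-loop reference for one attention layer (encoder and decoder share
# the same functional form): tanh transform, sigmoid logits, softmax over
# the neighbor set, weighted aggregation.
oracle_layer <- function(Hin, W, vs, vr, neighbors) {
  n <- nrow(Hin)
  d_out <- ncol(W)
  S <- matrix(0, n, d_out)
  for (i in seq_len(n)) S[i, ] <- tanh(as.vector(Hin[i, ] %*% W))
  Hout <- matrix(0, n, d_out)
  alpha_list <- vector("list", n)
  for (i in seq_len(n)) {
    Ni <- neighbors[[i]]
    cc <- vapply(Ni, function(j) {
      plogis(sum(vs * S[i, ]) + sum(vr * S[j, ]))
    }, 1)
    a <- exp(cc) / sum(exp(cc))
    alpha_list[[i]] <- a
    for (t in seq_along(Ni)) Hout[i, ] <- Hout[i, ] + a[t] * S[Ni[t], ]
  }
  list(Hout = Hout, alpha = alpha_list)
}

# Scalar-loop autoencoder loss oracle.
oracle_gate_loss <- function(X, Xhat, H, neighbors, lambda) {
  recon <- 0
  for (i in seq_len(nrow(X))) recon <- recon + sum((X[i, ] - Xhat[i, ])^2)
  struct <- 0
  for (i in seq_len(nrow(H))) {
    for (j in neighbors[[i]]) {
      struct <- struct + log(1 / (1 + exp(-sum(H[i, ] * H[j, ]))))
    }
  }
  recon - lambda * struct
}

write_edge_file <- function(lines, sep = "\t") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(gsub(",", sep, lines, fixed = TRUE), path)
  path
}
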