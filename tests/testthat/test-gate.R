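test_that("graph sparsification keeps self plus top-k neighbors with index tie-break", {
  nm <- c("a", "b", "c")
  S <- matrix(c(1, 0.9, 0.2, 0.9, 1, 0.5, 0.2, 0.5, 1), 3, 3)
  sm <- similarity_matrix(S, nm, "disease", "gapk")
  g <- build_graph(sm, diag(3), 1L)
  expect_equal(g$neighbors[[1]], c(1L, 2L))
  # tie between nodes 2 and 3 as neighbors of 1 -> lower index wins
  S2 <- matrix(c(1, 0.5, 0.5, 0.5, 1, 0.1, 0.5, 0.1, 1), 3, 3)
  g2 <- build_graph(similarity_matrix(S2, nm, "disease", "gapk"), diag(3), 1L)
  expect_equal(g2$neighbors[[1]], c(1L, 2L))
  # k = n - 1 -> complete neighbor sets
  g3 <- build_graph(sm, diag(3), 2L)
  expect_true(all(vapply(g3$neighbors, length, 1L) == 3L))
  expect_error(build_graph(sm, diag(3), 3L), "smaller than the node count")
})

test_that("attention weights are a proper distribution and match the loop oracle", {
  set.seed(7)
  g <- small_graph(n = 4, m = 5, k = 2, seed = 7)
  model <- gate_init(ncol(g$X), embedding_dim = 3L, seed = 2)
  aw <- attention_weights(model, g, g$X, layer = 1L, direction = "encode")
  sums <- as.vector(tapply(aw$alpha, aw$i, sum))
  expect_equal(sums, rep(1, g$n), tolerance = 1e-12)
  expect_true(all(aw$alpha > 0))

  orc <- oracle_layer(g$X, model$encoder[[1]]$W, model$encoder[[1]]$vs,
                      model$encoder[[1]]$vr, g$neighbors)
  expect_equal(aw$alpha, unlist(orc$alpha), tolerance = 1e-12, ignore_attr = TRUE)

  # singleton neighbor set -> weight exactly 1
  nm <- c("a", "b")
  sm <- similarity_matrix(diag(2), nm, "disease", "gapk")
  g1 <- build_graph(sm, matrix(c(1, 0, 0, 1), 2, 2), 0L)
  m1 <- gate_init(2L, embedding_dim = 2L, seed = 1)
  aw1 <- attention_weights(m1, g1, g1$X)
  expect_equal(aw1$alpha, c(1, 1))
})

test_that("encoder and decoder match nested-loop references on a 5-node fixture", {
  g <- small_graph(n = 5, m = 6, k = 2, seed = 3)
  model <- gate_init(ncol(g$X), embedding_dim = 4L, seed = 5)
  enc <- gate_encode(model, g)
  orc_e <- oracle_layer(g$X, model$encoder[[1]]$W, model$encoder[[1]]$vs,
                        model$encoder[[1]]$vr, g$neighbors)
  expect_equal(enc$embedding$H, orc_e$Hout, tolerance = 1e-10, ignore_attr = TRUE)

  dec <- gate_decode(model, enc$embedding, g)
  orc_d <- oracle_layer(orc_e$Hout, model$decoder[[1]]$W, model$decoder[[1]]$vs,
                        model$decoder[[1]]$vr, g$neighbors)
  expect_equal(dec$Xhat, orc_d$Hout, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("single-node-style propagation reduces to the closed form", {
  # with empty off-diagonal neighborhoods (k = 0), each node only attends
  # to itself: h = tanh(W' x)
  nm <- c("a", "b")
  sm <- similarity_matrix(diag(2), nm, "disease", "gapk")
  X <- matrix(c(0.3, -0.2, 0.8, 0.1), 2, 2)
  g <- build_graph(sm, X, 0L)
  model <- gate_init(2L, embedding_dim = 3L, seed = 9)
  enc <- gate_encode(model, g)
  expect_equal(enc$embedding$H, tanh(X %*% model$encoder[[1]]$W),
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("autoencoder loss matches closed forms and the scalar oracle", {
  g <- small_graph(n = 5, m = 6, k = 2, seed = 13)
  H <- matrix(0, g$n, 3)  # all inner products zero
  # perfect reconstruction, lambda 0 -> loss 0
  expect_equal(gate_loss(g, H, g$X, lambda = 0), 0)
  # zero inner products, perfect reconstruction, lambda 1 -> |E| * log 2
  expect_equal(gate_loss(g, H, g$X, lambda = 1), length(g$ei) * log(2),
    tolerance = 1e-12
  )
  # random instance vs scalar-loop oracle
  set.seed(21)
  H2 <- matrix(rnorm(g$n * 3), g$n, 3)
  Xhat <- g$X + matrix(rnorm(length(g$X), 0, 0.1), nrow(g$X))
  expect_equal(
    gate_loss(g, H2, Xhat, lambda = 0.7),
    oracle_gate_loss(g$X, Xhat, H2, g$neighbors, 0.7),
    tolerance = 1e-10
  )
  expect_error(gate_loss(g, H2, Xhat, lambda = -1), "nonnegative")
})

test_that("analytic gradients agree with central finite differences", {
  g <- small_graph(n = 5, m = 6, k = 2, seed = 17)
  model <- gate_init(ncol(g$X), embedding_dim = 3L, lambda = 0.5, seed = 23)
  lg <- mdalink:::gate_loss_grads(model, g)
  flat <- mdalink:::flatten_gate(model)
  eps <- 1e-6
  set.seed(1)
  for (nm in names(flat)) {
    for (k in sample(seq_along(flat[[nm]]), min(3, length(flat[[nm]])))) {
      f2 <- flat
      f2[[nm]][k] <- flat[[nm]][k] + eps
      lp <- mdalink:::gate_loss_grads(mdalink:::unflatten_gate(model, f2), g)$loss
      f2[[nm]][k] <- flat[[nm]][k] - eps
      lm_ <- mdalink:::gate_loss_grads(mdalink:::unflatten_gate(model, f2), g)$loss
      num <- (lp - lm_) / (2 * eps)
      expect_lt(abs(lg$grads[[nm]][k] - num), 1e-5 * max(1, abs(num)))
    }
  }
})

test_that("training is seed-deterministic and reduces the loss", {
  g <- small_graph(n = 12, m = 10, k = 3, seed = 29)
  t1 <- train_gate(g, embedding_dim = 4L, epochs = 60L, seed = 31)
  t2 <- train_gate(g, embedding_dim = 4L, epochs = 60L, seed = 31)
  expect_identical(t1$loss_trace, t2$loss_trace)
  expect_identical(t1$embedding$H, t2$embedding$H)
  expect_lt(t1$loss_trace[length(t1$loss_trace)], t1$loss_trace[1])
  # different seed -> different trajectory
  t3 <- train_gate(g, embedding_dim = 4L, epochs = 60L, seed = 32)
  expect_false(identical(t1$loss_trace, t3$loss_trace))
})

test_that("nodes with identical attributes and neighborhoods embed identically", {
  # nodes 1 and 2: same attribute rows, same neighbor sets including both
  X <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0), c(0, 1, 1))
  S <- matrix(0.2, 4, 4)
  S[1, 2] <- S[2, 1] <- 0.9
  S[3, 4] <- S[4, 3] <- 0.8
  diag(S) <- 1
  sm <- similarity_matrix(S, paste0("n", 1:4), "disease", "gapk")
  g <- build_graph(sm, X, 1L)
  expect_equal(sort(g$neighbors[[1]]), c(1L, 2L))
  expect_equal(sort(g$neighbors[[2]]), c(1L, 2L))
  model <- gate_init(3L, embedding_dim = 4L, seed = 37)
  enc <- gate_encode(model, g)
  expect_equal(enc$embedding$H[1, ], enc$embedding$H[2, ], tolerance = 1e-12)
})

test_that("pair features concatenate microbe then disease embeddings", {
  me <- structure(list(names = c("m1", "m2"), H = rbind(c(1, 2, 3), c(4, 5, 6))),
    class = "embedding_set"
  )
  de <- structure(list(names = c("d1", "d2"), H = rbind(c(7, 8), c(9, 10))),
    class = "embedding_set"
  )
  ds <- make_pair_features(me, de, cbind(2, 1))
  expect_equal(ncol(ds$X), 5L)  # 3 + 2
  expect_equal(unname(ds$X[1, ]), c(1, 2, 3, 9, 10))
  expect_error(make_pair_features(me, de, cbind(3, 1)), "disease index")
})

test_that("default embedding widths give 128-dimensional pair features", {
  g <- small_graph(n = 8, m = 7, k = 2, seed = 41)
  tr_d <- train_gate(g, epochs = 2L, seed = 1)
  expect_equal(ncol(tr_d$embedding$H), 64L)
  Y <- random_binary_Y(8, 7, 0.4)
  Sm <- side_similarity(Y, "microbe")
  gm <- build_graph(Sm, t(Y), 2L)
  tr_m <- train_gate(gm, epochs = 2L, seed = 1)
  ds <- make_pair_features(tr_m$embedding, tr_d$embedding, cbind(1, 1))
  expect_equal(ncol(ds$X), 128L)
})

test_that("trained reconstruction error falls well below the untrained model's", {
  # 60-node graph with low-rank block structure, default width and
  # learning rate, 100 epochs
  gen <- generate_associations(synthetic_spec(
    n_diseases = 60L, n_microbes = 40L, latent_rank = 4L,
    target_density = 0.1, seed = 43
  ))
  S <- side_similarity(gen$assoc$Y, "disease")
  g <- build_graph(S, gen$assoc$Y, 5L)
  recon_err <- function(model) {
    enc <- gate_encode(model, g)
    dec <- gate_decode(model, enc$embedding, g)
    sum((g$X - dec$Xhat)^2)
  }
  untrained <- gate_init(ncol(g$X), embedding_dim = 64L, seed = 47)
  tr <- train_gate(g, embedding_dim = 64L, epochs = 100L, seed = 47)
  expect_lte(recon_err(tr$model), 0.5 * recon_err(untrained))
})
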