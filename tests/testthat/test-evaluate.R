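test_that("AUC matches hand examples and handles perfect orderings", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(compute_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(compute_auc(c(0.9, 0.8, 0.3, 0.2), c(0, 0, 1, 1)), 0)
  expect_error(compute_auc(c(0.5, 0.6), c(1, 1)), "both classes")
})

test_that("AUC equals the O(n^2) Mann-Whitney oracle including ties", {
  set.seed(3)
  for (rep in 1:60) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) labels[1] <- 1
    if (sum(labels) == n) labels[1] <- 0
    expect_equal(compute_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("AUPR is 1 for perfect separation and matches a hand-worked tie case", {
  expect_equal(compute_aupr(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  # scores 0.9 > 0.5 = 0.5 > 0.1 with labels 1, 1, 0, 0:
  # threshold sweep: P=1 R=1/2; then the tied block adds one TP one FP
  # (P=2/3, R=1); area = 1/2*1 + 1/2*2/3 = 5/6
  expect_equal(compute_aupr(c(0.9, 0.5, 0.5, 0.1), c(1, 1, 0, 0)), 5 / 6)
  # random-ish sanity: AUPR at least the positive prevalence for a
  # constant scorer
  expect_equal(compute_aupr(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)
})

test_that("fold partitions are near-equal, deterministic and scheme-aware", {
  gen <- generate_associations(synthetic_spec(seed = 5))
  a39 <- bipartite_associations(
    paste0("d", 1:39), paste0("m", 1:8),
    {
      set.seed(1)
      random_binary_Y(39, 8, 0.3)
    }
  )
  folds <- make_folds(a39, "disease", 5L, seed = 2)
  expect_setequal(unlist(folds), 1:39)
  expect_setequal(lengths(folds), c(8, 8, 8, 8, 7))
  folds2 <- make_folds(a39, "disease", 5L, seed = 2)
  expect_identical(folds, folds2)

  # pair scheme partitions every cell
  fp <- make_folds(gen$assoc, "pair", 5L, seed = 3)
  expect_setequal(unlist(fp), seq_along(gen$assoc$Y))
  expect_true(max(lengths(fp)) - min(lengths(fp)) <= 1)

  expect_error(make_folds(a39, "microbe", 10L, seed = 1), "fewer items")
})

test_that("disease-scheme masking zeroes every held-out disease row", {
  gen <- generate_associations(synthetic_spec(seed = 7))
  folds <- make_folds(gen$assoc, "disease", 5L, seed = 11)
  mk <- mdalink:::mask_fold(gen$assoc, "disease", folds[[2]])
  expect_true(all(mk$Ytrain[folds[[2]], ] == 0))
  # non-held rows untouched
  keep <- setdiff(seq_len(nrow(gen$assoc$Y)), folds[[2]])
  expect_identical(mk$Ytrain[keep, ], gen$assoc$Y[keep, ])
  expect_setequal(mk$held, which(row(gen$assoc$Y) %in% folds[[2]]))
})

test_that("cross-validation is deterministic and summarizes fold metrics coherently", {
  gen <- generate_associations(synthetic_spec(
    n_diseases = 12L, n_microbes = 20L, latent_rank = 2L,
    target_density = 0.15, seed = 13
  ))
  cfg <- mda_config(
    embedding_dim = 8L, k_neighbors = 4L, gate_epochs = 10L,
    dnn_layers = c(16L, 1L), dnn_epochs = 10L, seed = 17
  )
  cv1 <- run_cv(gen$assoc, cfg, scheme = "pair", n_folds = 3L, repeats = 2L)
  cv2 <- run_cv(gen$assoc, cfg, scheme = "pair", n_folds = 3L, repeats = 2L)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_true(all(cv1$metrics$auc >= 0 & cv1$metrics$auc <= 1))
  expect_true(all(cv1$metrics$aupr >= 0 & cv1$metrics$aupr <= 1))
  g <- glance(cv1)
  expect_gte(g$mean_auc, min(cv1$metrics$auc))
  expect_lte(g$mean_auc, max(cv1$metrics$auc))
  expect_equal(nrow(tidy(cv1)), 6L)
  p <- ggplot2::autoplot(cv1)
  expect_s3_class(p, "ggplot")
})

test_that("candidate ranking is sorted, flags known pairs and reports near matches", {
  gen <- generate_associations(synthetic_spec(
    n_diseases = 10L, n_microbes = 15L, latent_rank = 2L,
    target_density = 0.2, seed = 19
  ))
  cfg <- mda_config(
    embedding_dim = 6L, k_neighbors = 3L, gate_epochs = 10L,
    dnn_layers = c(8L, 1L), dnn_epochs = 10L, seed = 23
  )
  fit <- fit_mda(gen$assoc, cfg)
  tab <- rank_candidates(fit, "disease_03", top_k = 30L)
  expect_lte(nrow(tab), 15L)  # fewer microbes than top_k
  expect_equal(tab$rank, seq_len(nrow(tab)))
  expect_true(all(diff(tab$score) <= 0))
  # known associations are flagged, not filtered
  known_names <- gen$assoc$microbe_names[gen$assoc$Y[3, ] == 1]
  expect_setequal(tab$microbe[tab$known], known_names)
  # case-insensitive matching, informative error with suggestions
  expect_equal(rank_candidates(fit, " DISEASE_03 ", 5L)$microbe, tab$microbe[1:5])
  expect_error(rank_candidates(fit, "disease_99"), "nearest matches")
})

test_that("tied candidate scores rank alphabetically", {
  fit <- structure(
    list(
      assoc = bipartite_associations(
        c("d1", "d2"), c("zeta", "alpha", "mid"),
        matrix(c(1, 0, 0, 0, 0, 0), 2, 3)
      ),
      score_matrix = matrix(c(0.5, 0.1, 0.5, 0.2, 0.9, 0.3), 2, 3,
        dimnames = list(c("d1", "d2"), c("zeta", "alpha", "mid"))
      )
    ),
    class = "mda_fit"
  )
  tab <- rank_candidates(fit, "d1", 3L)
  expect_equal(tab$microbe, c("mid", "alpha", "zeta"))  # 0.9, then tie broken a-z
})
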