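make_pair_ds <- function(X, label) {
  structure(
    list(
      pairs = tibble::tibble(
        disease = NA_integer_, microbe = NA_integer_,
        disease_name = NA_character_, microbe_name = NA_character_
      )[rep(1L, nrow(X)), ],
      X = X, label = label
    ),
    class = "pair_dataset"
  )
}

test_that("spy count is floor(t * |P|) with a minimum of one", {
  set.seed(3)
  X <- matrix(rnorm(450 * 4), 450, 4)
  spies <- select_spies(X, pu_config(t_fraction = 0.15, seed = 1))
  expect_length(spies, 67L)  # floor(0.15 * 450)
  spies_small <- select_spies(matrix(rnorm(5 * 2), 5, 2),
    pu_config(t_fraction = 0.1, n_clusters = 2L, seed = 1)
  )
  expect_length(spies_small, 1L)
})

test_that("spy selection is centroid-driven and seed-deterministic", {
  # single cluster, one point exactly at the centroid of a symmetric cloud
  X <- rbind(
    c(0, 0),
    c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
    c(2, 2), c(-2, -2), c(2, -2), c(-2, 2)
  )
  s <- select_spies(X, pu_config(t_fraction = 0.12, n_clusters = 1L, seed = 4))
  expect_equal(s, 1L)

  set.seed(9)
  Xr <- matrix(rnorm(60 * 5), 60, 5)
  s1 <- select_spies(Xr, pu_config(seed = 7))
  s2 <- select_spies(Xr, pu_config(seed = 7))
  expect_identical(s1, s2)

  expect_error(
    select_spies(matrix(rnorm(8), 4, 2), pu_config(n_clusters = 5L)),
    "smaller than n_clusters"
  )
})

test_that("outlier positives are not chosen as spies on a clustered fixture", {
  set.seed(13)
  core <- matrix(rnorm(45 * 3, sd = 0.3), 45, 3)
  outliers <- matrix(rnorm(5 * 3, mean = 8), 5, 3)
  X <- rbind(core, outliers)
  spies <- select_spies(X, pu_config(t_fraction = 0.2, n_clusters = 2L, seed = 5))
  # 10 spies from 50 positives; outliers (rows 46-50) form their own sparse
  # cluster with larger spread, so the central core supplies the spies
  expect_true(all(spies <= 45L))
})

test_that("the boosted scorer separates linearly separated classes and stays in [0, 1]", {
  set.seed(17)
  X <- rbind(
    cbind(rnorm(50, 1, 0.2), matrix(rnorm(50 * 3), 50, 3)),
    cbind(rnorm(50, -1, 0.2), matrix(rnorm(50 * 3), 50, 3))
  )
  sc <- score_all_pairs(X, 1:50, 51:100, pu_config(seed = 3))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(mean(sc[1:50]), mean(sc[51:100]))

  # identical features -> identical scores
  X0 <- matrix(1, 40, 3)
  sc0 <- score_all_pairs(X0, 1:20, 21:40, pu_config(seed = 3))
  expect_equal(max(sc0) - min(sc0), 0)

  expect_error(score_all_pairs(X, integer(0), 1:100), "no positives")
})

test_that("thresholding equals brute-force enumeration on random score maps", {
  set.seed(19)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    idx <- sample.int(n)
    n_spy <- sample(1:3, 1)
    spy <- idx[seq_len(n_spy)]
    unl <- idx[(n_spy + 1):n]
    got <- threshold_negatives(scores, spy, unl)
    a_min <- Inf
    for (s in spy) if (scores[s] < a_min) a_min <- scores[s]
    rn <- integer(0)
    for (x in unl) if (scores[x] < a_min) rn <- c(rn, x)
    expect_identical(got$A_min, a_min)
    expect_identical(sort(got$rn), sort(rn))
  }
})

test_that("threshold boundary cases honor the strict inequality", {
  got <- threshold_negatives(c(0.4, 0.7, 0.3, 0.5), spy_idx = 1:2, unlabeled_idx = 3:4)
  expect_equal(got$A_min, 0.4)
  expect_equal(got$rn, 3L)
  # a U pair scoring exactly A_min is excluded
  got2 <- threshold_negatives(c(0.4, 0.7, 0.4), spy_idx = 1:2, unlabeled_idx = 3L)
  expect_length(got2$rn, 0L)
  # all U at or above A_min -> empty RN
  got3 <- threshold_negatives(c(0.2, 0.9, 0.8), spy_idx = 1L, unlabeled_idx = 2:3)
  expect_length(got3$rn, 0L)
})

test_that("raising one unlabeled score never adds other pairs to RN", {
  set.seed(23)
  scores <- runif(30)
  spy <- 1:5
  unl <- 6:30
  base <- threshold_negatives(scores, spy, unl)$rn
  for (x in sample(unl, 5)) {
    sc2 <- scores
    sc2[x] <- sc2[x] + runif(1, 0, 1 - sc2[x])
    rn2 <- threshold_negatives(sc2, spy, unl)$rn
    expect_true(all(rn2 %in% base))
    expect_true(all(setdiff(base, x) %in% rn2))
  }
})

test_that("the full selection pipeline keeps its set contracts", {
  gt <- generate_pu_ground_truth(n_pairs = 200, separation = 3, seed = 29)
  pu <- run_pu(gt$dataset, pu_config(seed = 31))
  expect_true(all(pu$spies %in% pu$positives))
  expect_length(intersect(pu$rn, pu$positives), 0L)
  expect_true(all(pu$rn %in% pu$unlabeled))
  expect_lte(length(pu$rn), length(pu$unlabeled))
  expect_equal(pu$A_min, min(pu$scores[pu$spies]))
  expect_true(all(pu$scores[pu$rn] < pu$A_min))

  # determinism contract
  pu2 <- run_pu(gt$dataset, pu_config(seed = 31))
  expect_identical(pu$rn, pu2$rn)
  expect_identical(pu$scores, pu2$scores)

  g <- glance(pu)
  expect_equal(g$n_reliable_negative, length(pu$rn))
  td <- tidy(pu)
  expect_equal(sum(td$role == "spy"), length(pu$spies))
})

test_that("well-separated planted data yields high reliable-negative precision", {
  gt <- generate_pu_ground_truth(n_pairs = 300, separation = 4, seed = 37)
  pu <- run_pu(gt$dataset, pu_config(seed = 41))
  expect_gte(rn_precision(pu, gt$truth), 0.9)
})
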