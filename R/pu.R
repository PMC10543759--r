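#' Configuration for reliable-negative selection
#'
#' @param t_fraction fraction of the positive set used as spies (default
#'   0.15, the setting for HMDAD-scale data; 0.20 suits larger
#'   Disbiome-scale sets).
#' @param n_clusters K-means cluster count for spy selection (default 5).
#' @param nrounds,max_depth,eta gradient-boosted-tree scorer settings
#'   (defaults 100 trees, depth 6, learning rate 0.1).
#' @param seed RNG seed; the scorer runs single-threaded so results are
#'   reproducible.
#' @return list of class `pu_config`.
#' @export
pu_config <- function(t_fraction = 0.15, n_clusters = 5L, nrounds = 100L,
                      max_depth = 6L, eta = 0.1, seed = 1L) {
  if (t_fraction <= 0 || t_fraction >= 1) stop("t_fraction must be in (0, 1)")
  if (n_clusters < 1L) stop("n_clusters must be at least 1")
  structure(
    list(t_fraction = t_fraction, n_clusters = as.integer(n_clusters),
         nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
         eta = eta, seed = as.integer(seed)),
    class = "pu_config"
  )
}

#' Select spy positives by cluster centrality
#'
#' Clusters the positive pairs with K-means and picks the
#' `floor(t_fraction * |P|)` positives (at least one) closest to their own
#' cluster centroid as spies. Central positives resemble the hidden
#' positives in the unlabeled pool better than boundary outliers would, so
#' the minimum spy score gives a trustworthy negative-mining threshold.
#' Ties in distance break toward the lower pair index; results are
#' deterministic for a fixed seed.
#'
#' @param features numeric matrix of positive-pair features (rows = members
#'   of P, in pair-index order).
#' @param config a [pu_config()].
#' @return integer vector of row indices into `features` (the spy set S).
#' @export
select_spies <- function(features, config = pu_config()) {
  features <- as.matrix(features)
  n_pos <- nrow(features)
  if (n_pos < 2L) stop("need at least 2 positives")
  if (!all(is.finite(features))) stop("features must be finite")
  if (n_pos < config$n_clusters) {
    stop(sprintf("|P| = %d is smaller than n_clusters = %d", n_pos, config$n_clusters))
  }
  km <- with_seed(config$seed, {
    stats::kmeans(features, centers = config$n_clusters,
                  nstart = 5L, iter.max = 50L)
  })
  cent <- km$centers[km$cluster, , drop = FALSE]
  dist_to_centroid <- sqrt(rowSums((features - cent)^2))
  n_spies <- max(1L, floor(config$t_fraction * n_pos))
  order(dist_to_centroid, seq_len(n_pos))[seq_len(n_spies)]
}

#' Score all pairs with a gradient-boosted ensemble
#'
#' Fits gradient-boosted trees with the non-spy positives labeled 1 and the
#' unlabeled pool plus spies labeled 0, then returns the fitted class-1
#' probability for every pair. Runs single-threaded with a fixed seed so
#' scores are reproducible.
#'
#' @param X_all feature matrix for all pairs.
#' @param pos_idx row indices of training positives (P minus S).
#' @param neg_idx row indices of training "negatives" (U plus S).
#' @param config a [pu_config()].
#' @return numeric vector of scores in `[0, 1]`, one per row of `X_all`.
#' @export
score_all_pairs <- function(X_all, pos_idx, neg_idx, config = pu_config()) {
  if (length(pos_idx) == 0L) stop("no positives left after spy removal; lower t_fraction")
  if (length(neg_idx) == 0L) stop("unlabeled pool is empty")
  X_all <- as.matrix(X_all)
  tr <- c(pos_idx, neg_idx)
  y <- c(rep(1, length(pos_idx)), rep(0, length(neg_idx)))
  dtrain <- xgboost::xgb.DMatrix(X_all[tr, , drop = FALSE], label = y, nthread = 1L)
  booster <- with_seed(config$seed, {
    xgboost::xgb.train(
      params = list(
        objective = "binary:logistic", max_depth = config$max_depth,
        eta = config$eta, nthread = 1L, seed = config$seed
      ),
      data = dtrain, nrounds = config$nrounds, verbose = 0
    )
  })
  scores <- stats::predict(booster, X_all)
  pmin(pmax(as.numeric(scores), 0), 1)
}

#' Threshold unlabeled pairs at the minimum spy score
#'
#' `A_min` is the smallest score among the spies; every unlabeled pair
#' scoring strictly below `A_min` becomes a reliable negative. Spies were
#' genuine positives, so any unlabeled pair the scorer ranks below all of
#' them is very unlikely to be a hidden positive.
#'
#' @param scores numeric score vector over all pairs.
#' @param spy_idx indices of the spy set S (non-empty).
#' @param unlabeled_idx indices of the unlabeled pool U.
#' @return list with `A_min` and `rn` (reliable-negative indices, a subset
#'   of `unlabeled_idx`).
#' @export
threshold_negatives <- function(scores, spy_idx, unlabeled_idx) {
  if (length(spy_idx) == 0L) stop("spy set is empty")
  A_min <- min(scores[spy_idx])
  rn <- unlabeled_idx[scores[unlabeled_idx] < A_min]
  list(A_min = A_min, rn = rn)
}

#' Run the full reliable-negative selection algorithm
#'
#' Composition of [select_spies()], [score_all_pairs()] and
#' [threshold_negatives()] on a pair dataset whose labels mark known
#' associations (1) versus unlabeled pairs (`NA` or 0). The number of
#' reliable negatives is data-driven (whatever falls below the minimum spy
#' score), never forced to match the positive count.
#'
#' @param dataset a `pair_dataset` from [make_pair_features()].
#' @param config a [pu_config()].
#' @return An object of class `pu_result`: `spies`, `scores`, `A_min`,
#'   `rn`, `positives`, `unlabeled` (all indices into the dataset rows).
#' @export
run_pu <- function(dataset, config = pu_config()) {
  stopifnot(inherits(dataset, "pair_dataset"))
  P <- which(!is.na(dataset$label) & dataset$label == 1)
  U <- setdiff(seq_len(nrow(dataset$X)), P)
  if (length(P) < 2L) stop("need at least 2 positive pairs")
  if (length(U) < 1L) stop("need at least 1 unlabeled pair")
  spies_local <- select_spies(dataset$X[P, , drop = FALSE], config)
  S <- P[spies_local]
  scores <- score_all_pairs(dataset$X, setdiff(P, S), c(U, S), config)
  thr <- threshold_negatives(scores, S, U)
  structure(
    list(spies = S, scores = scores, A_min = thr$A_min, rn = thr$rn,
         positives = P, unlabeled = U, config = config),
    class = "pu_result"
  )
}

#' @export
print.pu_result <- function(x, ...) {
  cat(sprintf(
    "<pu_result> |P| = %d, |S| = %d spies, A_min = %.4f, |RN| = %d of %d unlabeled\n",
    length(x$positives), length(x$spies), x$A_min, length(x$rn), length(x$unlabeled)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pu_result <- function(x, ...) {
  n <- length(x$scores)
  role <- rep("unlabeled", n)
  role[x$positives] <- "positive"
  role[x$spies] <- "spy"
  role[x$rn] <- "reliable_negative"
  tibble::tibble(pair = seq_len(n), score = x$scores, role = role)
}

#' @exportS3Method generics::glance
glance.pu_result <- function(x, ...) {
  tibble::tibble(
    n_positive = length(x$positives), n_spies = length(x$spies),
    A_min = x$A_min, n_reliable_negative = length(x$rn),
    n_unlabeled = length(x$unlabeled)
  )
}
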