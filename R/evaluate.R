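#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted half; computed from midranks, which is exactly the
#' normalized Mann-Whitney U statistic.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 label vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' compute_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
compute_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step interpolation over score-sorted thresholds: pairs are swept in
#' decreasing score order (tied scores processed as one block) and the
#' area accumulates `(R_k - R_{k-1}) * P_k`.
#'
#' @inheritParams compute_auc
#' @return AUPR in `(0, 1]`.
#' @export
compute_aupr <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0L || sum(labels == 0) == 0L) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  grp <- match(scores, thr)
  tp_by_thr <- vapply(seq_along(thr), function(k) sum(labels[grp == k]), 1)
  n_by_thr <- vapply(seq_along(thr), function(k) sum(grp == k), 1)
  tp <- cumsum(tp_by_thr)
  pred_pos <- cumsum(n_by_thr)
  precision <- tp / pred_pos
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

#' Cross-validation fold assignment
#'
#' Partitions diseases, microbes, or individual matrix cells into
#' `n_folds` near-equal parts (sizes differ by at most one). In the
#' disease and microbe schemes a test fold holds out every pair involving
#' the held-out entities (cold start); in the pair scheme it holds out a
#' random fifth of all cells.
#'
#' @param assoc a [bipartite_associations] object.
#' @param scheme `"pair"`, `"disease"` or `"microbe"`.
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed; the same seed reproduces the same partition.
#' @return list of folds; each fold is an integer vector — disease indices,
#'   microbe indices, or flat cell indices of `Y` depending on the scheme.
#' @export
make_folds <- function(assoc, scheme = c("pair", "disease", "microbe"),
                       n_folds = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(assoc, "bipartite_associations"))
  n_items <- switch(scheme,
    disease = nrow(assoc$Y), microbe = ncol(assoc$Y),
    pair = length(assoc$Y)
  )
  if (n_items < n_folds) stop("fewer items than folds")
  perm <- with_seed(seed, sample.int(n_items))
  fold_of <- rep(seq_len(n_folds), length.out = n_items)  # sizes differ by <= 1
  lapply(seq_len(n_folds), function(f) sort(perm[fold_of == f]))
}

# Training copy of Y with the held-out block zeroed, plus the flat cell
# indices of the held-out block.
mask_fold <- function(assoc, scheme, fold) {
  Y <- assoc$Y
  held <- switch(scheme,
    disease = which(row(Y) %in% fold),
    microbe = which(col(Y) %in% fold),
    pair = fold
  )
  Ytr <- Y
  Ytr[held] <- 0
  list(Ytrain = Ytr, held = held)
}

#' Pipeline hyperparameters
#'
#' Bundles every stage's settings with one master seed that is fanned out
#' deterministically to the stages. Defaults follow the published protocol:
#' 64-dimensional embeddings on each side (pair features of width 128), spy
#' fraction 0.15, DNN layers 128-100-100-50-1 with learning rate 0.001 and
#' dropout 0.2, 300 DNN epochs.
#'
#' @param embedding_dim per-side embedding width (default 64).
#' @param k_neighbors graph sparsification neighbor count (default 10).
#' @param gate_epochs autoencoder training epochs (default 200).
#' @param lambda autoencoder structure-loss weight (default 1).
#' @param t_fraction spy fraction of the positive set (default 0.15).
#' @param n_clusters K-means clusters for spy selection (default 5).
#' @param dnn_layers hidden + output layer widths after the input layer
#'   (default `c(100, 100, 50, 1)`).
#' @param dnn_epochs DNN training epochs (default 300).
#' @param learning_rate DNN/autoencoder learning rate (default 0.001).
#' @param dropout DNN dropout rate (default 0.2).
#' @param batch_size DNN mini-batch size (default 32).
#' @param seed master seed.
#' @return list of class `mda_config`.
#' @export
mda_config <- function(embedding_dim = 64L, k_neighbors = 10L,
                       gate_epochs = 200L, lambda = 1,
                       t_fraction = 0.15, n_clusters = 5L,
                       dnn_layers = c(100L, 100L, 50L, 1L),
                       dnn_epochs = 300L, learning_rate = 0.001,
                       dropout = 0.2, batch_size = 32L, seed = 1L) {
  structure(
    list(
      embedding_dim = as.integer(embedding_dim),
      k_neighbors = as.integer(k_neighbors),
      gate_epochs = as.integer(gate_epochs), lambda = lambda,
      t_fraction = t_fraction, n_clusters = as.integer(n_clusters),
      dnn_layers = as.integer(dnn_layers),
      dnn_epochs = as.integer(dnn_epochs),
      learning_rate = learning_rate, dropout = dropout,
      batch_size = as.integer(batch_size), seed = as.integer(seed)
    ),
    class = "mda_config"
  )
}

# Embeddings for both sides from a (possibly fold-masked) association
# matrix: kernel + fusion, kNN graph over fused similarity with the
# association profile as node attributes, then autoencoder training.
embed_sides <- function(Ytrain, config, functional_d = NULL, functional_m = NULL,
                        disease_names = NULL, microbe_names = NULL) {
  if (is.null(disease_names)) disease_names <- rownames(Ytrain)
  if (is.null(microbe_names)) microbe_names <- colnames(Ytrain)
  Sd <- side_similarity(Ytrain, "disease", functional_d)
  Sm <- side_similarity(Ytrain, "microbe", functional_m)
  kd <- min(config$k_neighbors, nrow(Ytrain) - 1L)
  km <- min(config$k_neighbors, ncol(Ytrain) - 1L)
  gd <- build_graph(Sd, Ytrain, kd)
  gm <- build_graph(Sm, t(Ytrain), km)
  fit_d <- train_gate(gd,
    embedding_dim = config$embedding_dim, epochs = config$gate_epochs,
    learning_rate = config$learning_rate, lambda = config$lambda,
    seed = derive_seed(config$seed, "gate_disease")
  )
  fit_m <- train_gate(gm,
    embedding_dim = config$embedding_dim, epochs = config$gate_epochs,
    learning_rate = config$learning_rate, lambda = config$lambda,
    seed = derive_seed(config$seed, "gate_microbe")
  )
  fit_d$embedding$names <- disease_names
  fit_m$embedding$names <- microbe_names
  list(disease = fit_d$embedding, microbe = fit_m$embedding,
       gate_disease = fit_d, gate_microbe = fit_m,
       similarity_disease = Sd, similarity_microbe = Sm)
}

# All-pairs feature set for a matrix of size n x m, in flat column-major
# cell order so that cell index k maps to row k of the dataset.
all_pair_dataset <- function(emb, Ytrain, label = NULL) {
  n <- nrow(Ytrain); m <- ncol(Ytrain)
  pairs <- cbind(rep(seq_len(n), m), rep(seq_len(m), each = n))
  make_pair_features(emb$microbe, emb$disease, pairs, label)
}

subset_pair_dataset <- function(dataset, idx, label = NULL) {
  structure(
    list(
      pairs = dataset$pairs[idx, , drop = FALSE],
      X = dataset$X[idx, , drop = FALSE],
      label = if (is.null(label)) dataset$label[idx] else as.numeric(label)
    ),
    class = "pair_dataset"
  )
}

# Train the classifier for one training matrix: embeddings -> PU reliable
# negatives -> DNN. The unlabeled pool is every cell not marked positive in
# Ytrain, exactly as the selection algorithm defines U over all unknown
# pairs; in cross-validation this includes held-out cells, whose labels are
# never consulted (that is the point of treating them as unlabeled).
# `negatives` overrides PU with explicit negative cells (ablation arm).
fit_stage <- function(Ytrain, config, emb = NULL, negatives = NULL) {
  if (is.null(emb)) emb <- embed_sides(Ytrain, config)
  ds_all <- all_pair_dataset(emb, Ytrain)
  pos_cells <- which(Ytrain == 1)
  unl_cells <- setdiff(seq_along(Ytrain), pos_cells)
  pu <- NULL
  if (is.null(negatives)) {
    ds_train <- subset_pair_dataset(
      ds_all, c(pos_cells, unl_cells),
      label = c(rep(1, length(pos_cells)), rep(NA, length(unl_cells)))
    )
    pu <- run_pu(ds_train, pu_config(
      t_fraction = config$t_fraction, n_clusters = config$n_clusters,
      seed = derive_seed(config$seed, "pu")
    ))
    negatives <- c(pos_cells, unl_cells)[pu$rn]
    if (length(negatives) == 0L) {
      warning("PU selection returned no reliable negatives; sampling random unlabeled pairs")
      negatives <- with_seed(
        derive_seed(config$seed, "rn_fallback"),
        sample(unl_cells, min(length(pos_cells), length(unl_cells)))
      )
    }
  }
  tr_idx <- c(pos_cells, negatives)
  y <- c(rep(1, length(pos_cells)), rep(0, length(negatives)))
  dnn <- build_dnn(
    layer_sizes = c(ncol(ds_all$X), config$dnn_layers),
    dropout = config$dropout, learning_rate = config$learning_rate,
    seed = derive_seed(config$seed, "dnn_init")
  )
  fit <- train_dnn(dnn, ds_all$X[tr_idx, , drop = FALSE], y,
    epochs = config$dnn_epochs, batch_size = config$batch_size,
    seed = derive_seed(config$seed, "dnn_train")
  )
  list(emb = emb, dataset = ds_all, pu = pu, negatives = negatives,
       model = fit$model, loss_trace = fit$loss_trace)
}

#' Cross-validated evaluation of the full pipeline
#'
#' For every repeat and fold: mask the held-out block of the association
#' matrix, recompute kernel similarity and embeddings from the masked
#' (training) matrix only, rerun reliable-negative selection and classifier
#' training on training cells only, then score the held-out cells. Held-out
#' known associations are the test positives; all other held-out cells are
#' test negatives. Folds whose test block contains no positive are skipped
#' with a warning.
#'
#' @param assoc a [bipartite_associations] object.
#' @param config an [mda_config()].
#' @param scheme CV scheme: `"pair"`, `"disease"` or `"microbe"`.
#' @param n_folds folds per repeat (default 5).
#' @param repeats number of repeated partitions (default 20).
#' @return object of class `cv_result` with a tibble of per-fold metrics.
#' @export
run_cv <- function(assoc, config = mda_config(),
                   scheme = c("pair", "disease", "microbe"),
                   n_folds = 5L, repeats = 20L) {
  scheme <- match.arg(scheme)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    folds <- make_folds(assoc, scheme, n_folds,
      seed = derive_seed(config$seed, paste0("folds", rep_i))
    )
    for (f in seq_len(n_folds)) {
      mk <- mask_fold(assoc, scheme, folds[[f]])
      test_labels <- assoc$Y[mk$held]
      if (sum(test_labels) == 0) {
        warning(sprintf("repeat %d fold %d has no test positives; skipped", rep_i, f))
        next
      }
      fold_cfg <- config
      fold_cfg$seed <- derive_seed(config$seed, sprintf("rep%d_fold%d", rep_i, f))
      st <- fit_stage(mk$Ytrain, fold_cfg)
      sc <- predict_scores(st$model, st$dataset$X[mk$held, , drop = FALSE])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repeat_ = rep_i, fold = f,
        auc = compute_auc(sc, test_labels),
        aupr = compute_aupr(sc, test_labels),
        n_test = length(test_labels), n_test_pos = sum(test_labels),
        n_rn = length(st$negatives)
      )
    }
  }
  if (length(rows) == 0L) stop("no usable folds")
  metrics <- dplyr::bind_rows(rows)
  structure(
    list(metrics = metrics, scheme = scheme, n_folds = n_folds,
         repeats = repeats, config = config),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> scheme = %s, %d folds x %d repeats (%d usable)\n  mean AUC  %.4f (sd %.4f)\n  mean AUPR %.4f (sd %.4f)\n",
    x$scheme, x$n_folds, x$repeats, nrow(x$metrics),
    mean(x$metrics$auc), stats::sd(x$metrics$auc),
    mean(x$metrics$aupr), stats::sd(x$metrics$aupr)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, n_folds = x$n_folds, repeats = x$repeats,
    mean_auc = mean(x$metrics$auc), sd_auc = stats::sd(x$metrics$auc),
    mean_aupr = mean(x$metrics$aupr), sd_aupr = stats::sd(x$metrics$aupr)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, ...) {
  df <- tidyr_longer_metrics(object$metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      title = sprintf("Cross-validation (%s scheme)", object$scheme),
      x = NULL, y = "value"
    ) +
    ggplot2::theme_minimal()
}

# minimal long-format helper (avoids a tidyr hard dependency for one call)
tidyr_longer_metrics <- function(metrics) {
  dplyr::bind_rows(
    tibble::tibble(metric = "AUC", value = metrics$auc),
    tibble::tibble(metric = "AUPR", value = metrics$aupr)
  )
}

#' Ablation of the reliable-negative selection step
#'
#' Runs the cross-validation protocol twice with shared fold partitions,
#' similarities and embeddings: once with reliable negatives from the
#' spy-based PU algorithm, once with uniformly random unlabeled training
#' cells of the same count. Reports both arms' fold-level metrics and the
#' paired difference.
#'
#' @inheritParams run_cv
#' @return object of class `pu_ablation`: `pu` and `random` are
#'   `cv_result`s, `delta_auc` / `delta_aupr` the mean paired differences.
#' @export
ablate_pu <- function(assoc, config = mda_config(),
                      scheme = c("pair", "disease", "microbe"),
                      n_folds = 5L, repeats = 1L) {
  scheme <- match.arg(scheme)
  rows_pu <- list(); rows_rand <- list()
  for (rep_i in seq_len(repeats)) {
    folds <- make_folds(assoc, scheme, n_folds,
      seed = derive_seed(config$seed, paste0("folds", rep_i))
    )
    for (f in seq_len(n_folds)) {
      mk <- mask_fold(assoc, scheme, folds[[f]])
      test_labels <- assoc$Y[mk$held]
      if (sum(test_labels) == 0) next
      fold_cfg <- config
      fold_cfg$seed <- derive_seed(config$seed, sprintf("rep%d_fold%d", rep_i, f))
      emb <- embed_sides(mk$Ytrain, fold_cfg)
      st_pu <- fit_stage(mk$Ytrain, fold_cfg, emb = emb)
      pos_cells <- which(mk$Ytrain == 1)
      unl_cells <- setdiff(seq_along(assoc$Y), pos_cells)
      rand_neg <- with_seed(
        derive_seed(fold_cfg$seed, "random_negatives"),
        sample(unl_cells, min(length(st_pu$negatives), length(unl_cells)))
      )
      st_rand <- fit_stage(mk$Ytrain, fold_cfg, emb = emb, negatives = rand_neg)
      sc_pu <- predict_scores(st_pu$model, st_pu$dataset$X[mk$held, , drop = FALSE])
      sc_rand <- predict_scores(st_rand$model, st_rand$dataset$X[mk$held, , drop = FALSE])
      rows_pu[[length(rows_pu) + 1L]] <- tibble::tibble(
        repeat_ = rep_i, fold = f,
        auc = compute_auc(sc_pu, test_labels),
        aupr = compute_aupr(sc_pu, test_labels),
        n_test = length(test_labels), n_test_pos = sum(test_labels),
        n_rn = length(st_pu$negatives)
      )
      rows_rand[[length(rows_rand) + 1L]] <- tibble::tibble(
        repeat_ = rep_i, fold = f,
        auc = compute_auc(sc_rand, test_labels),
        aupr = compute_aupr(sc_rand, test_labels),
        n_test = length(test_labels), n_test_pos = sum(test_labels),
        n_rn = length(rand_neg)
      )
    }
  }
  if (length(rows_pu) == 0L) stop("no usable folds")
  mk_res <- function(rows) {
    structure(
      list(metrics = dplyr::bind_rows(rows), scheme = scheme,
           n_folds = n_folds, repeats = repeats, config = config),
      class = "cv_result"
    )
  }
  pu <- mk_res(rows_pu); rand <- mk_res(rows_rand)
  structure(
    list(
      pu = pu, random = rand,
      delta_auc = mean(pu$metrics$auc - rand$metrics$auc),
      delta_aupr = mean(pu$metrics$aupr - rand$metrics$aupr)
    ),
    class = "pu_ablation"
  )
}

#' @export
print.pu_ablation <- function(x, ...) {
  cat(sprintf(
    "<pu_ablation> mean AUC: PU %.4f vs random %.4f (delta %+.4f)\n               mean AUPR: PU %.4f vs random %.4f (delta %+.4f)\n",
    mean(x$pu$metrics$auc), mean(x$random$metrics$auc), x$delta_auc,
    mean(x$pu$metrics$aupr), mean(x$random$metrics$aupr), x$delta_aupr
  ))
  invisible(x)
}

#' Fit the full pipeline on the complete association matrix
#'
#' Trains similarity, embeddings, reliable-negative selection and the
#' classifier on all observed data and scores every microbe-disease pair;
#' this is the object used for prospective candidate ranking.
#'
#' @param assoc a [bipartite_associations] object.
#' @param config an [mda_config()].
#' @param functional_d,functional_m optional functional
#'   [similarity_matrix] inputs for each side.
#' @return object of class `mda_fit`.
#' @export
fit_mda <- function(assoc, config = mda_config(),
                    functional_d = NULL, functional_m = NULL) {
  stopifnot(inherits(assoc, "bipartite_associations"))
  emb <- embed_sides(assoc$Y, config, functional_d, functional_m,
                     assoc$disease_names, assoc$microbe_names)
  st <- fit_stage(assoc$Y, config, emb = emb)
  scores <- predict_scores(st$model, st$dataset$X)
  structure(
    list(assoc = assoc, config = config, emb = emb, pu = st$pu,
         model = st$model, dataset = st$dataset,
         score_matrix = matrix(scores, nrow(assoc$Y), ncol(assoc$Y),
                               dimnames = dimnames(assoc$Y))),
    class = "mda_fit"
  )
}

#' @export
print.mda_fit <- function(x, ...) {
  cat(sprintf(
    "<mda_fit> %d diseases x %d microbes; |RN| = %d; mean score %.3f\n",
    nrow(x$score_matrix), ncol(x$score_matrix),
    if (is.null(x$pu)) NA_integer_ else length(x$pu$rn),
    mean(x$score_matrix)
  ))
  invisible(x)
}

#' Rank candidate microbes for a disease
#'
#' Scores every microbe against the named disease with the fitted
#' classifier and returns the top of the ranking, ties broken
#' alphabetically by microbe name. Microbes with known associations are
#' flagged but kept at their predicted rank.
#'
#' @param fit an [fit_mda()] object.
#' @param disease disease name (matched case-insensitively after trimming).
#' @param top_k rows to return (default 30; fewer if there are fewer
#'   microbes).
#' @return tibble with `rank`, `microbe`, `score`, `known`.
#' @export
rank_candidates <- function(fit, disease, top_k = 30L) {
  stopifnot(inherits(fit, "mda_fit"))
  keys <- name_key(fit$assoc$disease_names)
  i <- match(name_key(disease), keys)
  if (is.na(i)) {
    near <- fit$assoc$disease_names[utils::head(
      order(utils::adist(name_key(disease), keys)), 3L
    )]
    stop(sprintf(
      "unknown disease '%s'; nearest matches: %s",
      disease, paste(near, collapse = ", ")
    ))
  }
  sc <- fit$score_matrix[i, ]
  ord <- order(-sc, fit$assoc$microbe_names)
  k <- min(top_k, length(sc))
  idx <- ord[seq_len(k)]
  tibble::tibble(
    rank = seq_len(k),
    microbe = fit$assoc$microbe_names[idx],
    score = unname(sc[idx]),
    known = fit$assoc$Y[i, idx] == 1
  )
}
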