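#' Run the full pipeline end to end and write artifacts
#'
#' Orchestrates similarity computation, embedding, reliable-negative
#' selection, classifier training and (optionally) cross-validated
#' evaluation from one configuration, writing every artifact as delimited
#' text under `out_dir` together with a JSON manifest. The manifest
#' records the configuration, the master seed and the MD5 checksum of each
#' artifact; a rerun with the same inputs and seed reproduces the
#' checksums bit-identically.
#'
#' @param edges path to an edge-list file ([load_associations()] format),
#'   or a [bipartite_associations] object.
#' @param out_dir output directory (created if needed).
#' @param config an [mda_config()].
#' @param functional_d,functional_m optional paths to functional
#'   similarity matrix files for the disease / microbe side.
#' @param cv_scheme optional CV scheme to evaluate (`"pair"`, `"disease"`,
#'   `"microbe"`) or `NULL` to skip evaluation.
#' @param cv_repeats repeats for the evaluation stage (default 1).
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(edges, out_dir, config = mda_config(),
                         functional_d = NULL, functional_m = NULL,
                         cv_scheme = NULL, cv_repeats = 1L) {
  assoc <- if (inherits(edges, "bipartite_associations")) {
    edges
  } else {
    if (!file.exists(edges)) stop("config validation: edge file not found: ", edges)
    load_associations(edges)
  }
  fd <- if (is.null(functional_d)) NULL else {
    M <- read_matrix(functional_d, square = TRUE)
    similarity_matrix(M, assoc$disease_names, "disease", "functional")
  }
  fm <- if (is.null(functional_m)) NULL else {
    M <- read_matrix(functional_m, square = TRUE)
    similarity_matrix(M, assoc$microbe_names, "microbe", "functional")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  put <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    artifacts[name] <<- unname(tools::md5sum(path))
    path
  }

  message("stage: similarity + embedding")
  fit <- fit_mda(assoc, config, fd, fm)
  put("similarity_disease.tsv", function(p) write_matrix(fit$emb$similarity_disease$S, p))
  put("similarity_microbe.tsv", function(p) write_matrix(fit$emb$similarity_microbe$S, p))
  emb_d <- fit$emb$disease$H
  dimnames(emb_d) <- list(assoc$disease_names, paste0("e", seq_len(ncol(emb_d))))
  emb_m <- fit$emb$microbe$H
  dimnames(emb_m) <- list(assoc$microbe_names, paste0("e", seq_len(ncol(emb_m))))
  put("embedding_disease.tsv", function(p) write_matrix(emb_d, p))
  put("embedding_microbe.tsv", function(p) write_matrix(emb_m, p))

  message("stage: reliable-negative selection")
  if (!is.null(fit$pu)) {
    pu_tab <- as.data.frame(tidy(fit$pu))
    put("pu_scores.tsv", function(p) {
      utils::write.table(pu_tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  message("stage: pair scoring")
  put("score_matrix.tsv", function(p) write_matrix(fit$score_matrix, p))

  cv_summary <- NULL
  if (!is.null(cv_scheme)) {
    message("stage: cross-validation (", cv_scheme, ")")
    cv <- run_cv(assoc, config, scheme = cv_scheme, repeats = cv_repeats)
    cv_summary <- as.list(glance(cv))
    put("cv_metrics.tsv", function(p) {
      utils::write.table(as.data.frame(cv$metrics), p,
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    })
  }

  manifest <- list(
    package = "mdalink",
    seed = config$seed,
    config = unclass(config),
    n_diseases = nrow(assoc$Y), n_microbes = ncol(assoc$Y),
    n_associations = sum(assoc$Y),
    A_min = if (is.null(fit$pu)) NULL else fit$pu$A_min,
    n_reliable_negatives = if (is.null(fit$pu)) NULL else length(fit$pu$rn),
    cv = cv_summary,
    artifacts = as.list(artifacts)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}
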