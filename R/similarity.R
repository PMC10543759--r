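#' Similarity matrix container
#'
#' A square symmetric matrix of pairwise similarities in `[0, 1]` for one
#' side of the bipartite network, tagged by side and kind.
#'
#' @param S square numeric matrix with entries in `[0, 1]`, symmetric to
#'   1e-10.
#' @param names entity names (row/column order of `S`).
#' @param side `"disease"` or `"microbe"`.
#' @param kind `"functional"`, `"gapk"` or `"fused"`.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(S, names, side = c("disease", "microbe"),
                              kind = c("functional", "gapk", "fused")) {
  side <- match.arg(side)
  kind <- match.arg(kind)
  S <- as.matrix(S)
  names <- as.character(names)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (nrow(S) != length(names)) stop("names length must match matrix dimension")
  if (max(abs(S - t(S))) > 1e-10) stop("similarity matrix must be symmetric")
  if (min(S) < -1e-12 || max(S) > 1 + 1e-12) stop("similarities must lie in [0, 1]")
  S <- pmin(pmax((S + t(S)) / 2, 0), 1)
  if (kind %in% c("gapk", "fused") && max(abs(diag(S) - 1)) > 1e-10) {
    stop("gapk/fused similarity must have unit diagonal")
  }
  dimnames(S) <- list(names, names)
  structure(list(S = S, names = names, side = side, kind = kind),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "<similarity_matrix> %s/%s, %d x %d, mean off-diagonal %.4f\n",
    x$side, x$kind, nrow(x$S), ncol(x$S),
    mean(x$S[row(x$S) != col(x$S)])
  ))
  invisible(x)
}

profiles_for_side <- function(Y, side) {
  if (side == "disease") Y else t(Y)
}

#' Gaussian association-profile kernel bandwidth
#'
#' The kernel bandwidth is normalized by the mean squared norm of the
#' association profiles: `theta = n / sum_i ||V_i||^2`, where `V_i` is the
#' i-th row profile (disease side) or column profile (microbe side) of the
#' binary association matrix and `n` is the number of profiles. With this
#' normalization an average-sized profile contributes a unit-scale exponent.
#'
#' @param Y binary association matrix (diseases x microbes) or a
#'   [bipartite_associations] object.
#' @param side which side's profiles to use: `"disease"` (rows) or
#'   `"microbe"` (columns).
#' @return positive scalar bandwidth.
#' @export
gapk_bandwidth <- function(Y, side = c("disease", "microbe")) {
  side <- match.arg(side)
  if (inherits(Y, "bipartite_associations")) Y <- Y$Y
  P <- profiles_for_side(Y, side)
  total <- sum(P^2)
  if (total == 0) stop("bandwidth undefined: all association profiles are zero")
  nrow(P) / total
}

#' Gaussian association-profile kernel similarity
#'
#' Radial-basis similarity between binary association profiles:
#' `G[i, j] = exp(-theta * ||V_i - V_j||^2)` with bandwidth from
#' [gapk_bandwidth()]. The result is symmetric with unit diagonal.
#'
#' @inheritParams gapk_bandwidth
#' @return A [similarity_matrix] of kind `"gapk"`.
#' @export
#' @examples
#' y <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("d1", "d2"), c("m1", "m2")))
#' gapk_similarity(y, "disease")$S
gapk_similarity <- function(Y, side = c("disease", "microbe")) {
  side <- match.arg(side)
  nm <- NULL
  if (inherits(Y, "bipartite_associations")) {
    nm <- if (side == "disease") Y$disease_names else Y$microbe_names
    Y <- Y$Y
  }
  theta <- gapk_bandwidth(Y, side)
  P <- profiles_for_side(Y, side)
  if (is.null(nm)) {
    nm <- rownames(P)
    if (is.null(nm)) nm <- paste0(substr(side, 1, 1), seq_len(nrow(P)))
  }
  # ||Vi - Vj||^2 = ||Vi||^2 + ||Vj||^2 - 2 Vi.Vj, clipped at 0 for roundoff
  sq <- rowSums(P^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  G <- exp(-theta * D2)
  G <- (G + t(G)) / 2
  diag(G) <- 1
  similarity_matrix(G, nm, side = side, kind = "gapk")
}

#' Fuse functional and kernel similarity
#'
#' Entrywise integration of a functional similarity matrix with the
#' association-profile kernel: where the functional similarity is nonzero
#' the fused value is the arithmetic mean of the two, elsewhere it is the
#' kernel value alone. Structural zeros in sparse functional matrices thus
#' fall back to the kernel rather than dragging the average down. When no
#' functional matrix is available the fused similarity equals the kernel.
#'
#' @param gapk a [similarity_matrix] of kind `"gapk"`.
#' @param functional optional [similarity_matrix] of kind `"functional"`
#'   for the same side with identical name ordering, or `NULL`.
#' @return A [similarity_matrix] of kind `"fused"` (unit diagonal).
#' @export
fuse_similarity <- function(gapk, functional = NULL) {
  stopifnot(inherits(gapk, "similarity_matrix"), gapk$kind == "gapk")
  G <- gapk$S
  if (is.null(functional)) {
    S <- G
  } else {
    stopifnot(inherits(functional, "similarity_matrix"))
    if (functional$side != gapk$side) stop("similarity sides differ")
    if (!identical(functional$names, gapk$names)) {
      stop("name ordering of functional and gapk similarity differs")
    }
    Fm <- functional$S
    S <- ifelse(Fm != 0, (Fm + G) / 2, G)
  }
  diag(S) <- 1
  similarity_matrix(S, gapk$names, side = gapk$side, kind = "fused")
}

#' Fused similarity for one side in a single call
#'
#' Convenience wrapper: kernel similarity from the association matrix, then
#' fusion with an optional functional matrix.
#'
#' @inheritParams gapk_bandwidth
#' @param functional optional functional [similarity_matrix] or `NULL`.
#' @return A [similarity_matrix] of kind `"fused"`.
#' @export
side_similarity <- function(Y, side = c("disease", "microbe"), functional = NULL) {
  side <- match.arg(side)
  fuse_similarity(gapk_similarity(Y, side), functional)
}
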