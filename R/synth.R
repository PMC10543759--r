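#' Specification for synthetic bipartite association data
#'
#' Describes a sparse binary association matrix with low-rank latent block
#' structure: each disease and each microbe loads mainly on one of
#' `latent_rank` latent communities and association propensity is the
#' inner product of the loadings. Defaults emulate a small curated MDA
#' database (tens of diseases, low hundreds of microbes, ~4% density).
#'
#' @param n_diseases,n_microbes matrix dimensions (default 40 x 120).
#' @param latent_rank number of latent communities (default 4); at most
#'   `min(n_diseases, n_microbes)`.
#' @param target_density fraction of cells set to 1 before noise
#'   (default 0.04).
#' @param noise_rate fraction of cells whose value is flipped after
#'   thresholding (default 0).
#' @param seed RNG seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_diseases = 40L, n_microbes = 120L,
                           latent_rank = 4L, target_density = 0.04,
                           noise_rate = 0, seed = 1L) {
  if (latent_rank > min(n_diseases, n_microbes)) {
    stop("latent_rank must not exceed min(n_diseases, n_microbes)")
  }
  if (target_density <= 0 || target_density >= 1) stop("target_density must be in (0, 1)")
  if (noise_rate < 0 || noise_rate >= 1) stop("noise_rate must be in [0, 1)")
  if (target_density * n_diseases * n_microbes < 10) {
    stop("infeasible density: fewer than 10 expected associations")
  }
  structure(
    list(n_diseases = as.integer(n_diseases), n_microbes = as.integer(n_microbes),
         latent_rank = as.integer(latent_rank), target_density = target_density,
         noise_rate = noise_rate, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic association matrix with known structure
#'
#' Draws nonnegative block-dominant latent factors `U` (diseases x rank)
#' and `V` (microbes x rank), forms the propensity matrix `P = U V'`, sets
#' the cells above the `(1 - target_density)` propensity quantile to 1,
#' then flips a `noise_rate` fraction of random cells. Returns both the
#' observed binary matrix and the ground-truth propensities so recovery
#' can be scored.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `assoc` (a [bipartite_associations]) and `propensity`
#'   (the latent matrix `P`).
#' @export
generate_associations <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_diseases; m <- spec$n_microbes; r <- spec$latent_rank
  with_seed(spec$seed, {
    block_d <- sample(rep_len(seq_len(r), n))
    block_m <- sample(rep_len(seq_len(r), m))
    # block-dominant nonnegative loadings: strong on own community,
    # weak baseline elsewhere
    U <- matrix(stats::runif(n * r, 0, 0.15), n, r)
    V <- matrix(stats::runif(m * r, 0, 0.15), m, r)
    U[cbind(seq_len(n), block_d)] <- stats::runif(n, 0.7, 1.3)
    V[cbind(seq_len(m), block_m)] <- stats::runif(m, 0.7, 1.3)
    P <- U %*% t(V)
    tau <- stats::quantile(P, 1 - spec$target_density, names = FALSE)
    Y <- (P > tau) * 1
    if (spec$noise_rate > 0) {
      n_flip <- round(spec$noise_rate * n * m)
      flip <- sample.int(n * m, n_flip)
      Y[flip] <- 1 - Y[flip]
    }
    assoc <- bipartite_associations(
      sprintf("disease_%02d", seq_len(n)),
      sprintf("microbe_%03d", seq_len(m)),
      Y
    )
    list(assoc = assoc, propensity = P,
         block_disease = block_d, block_microbe = block_m)
  })
}

#' Ground-truth harness for the reliable-negative selector
#'
#' Generates pair features from two Gaussians separated by `separation`
#' standard deviations (labeled positives and planted true negatives) plus
#' a small overlap group drawn midway between the class means — stand-ins
#' for the hidden positives that sparse association databases leave
#' unlabeled. The unlabeled pool mixes the true negatives with the overlap
#' group; the hidden truth is recorded so reliable-negative precision can
#' be scored.
#'
#' @param n_pairs total pair count (default 300).
#' @param separation distance between class means in units of the feature
#'   standard deviation (default 4).
#' @param dim feature dimension (default 16).
#' @param pos_fraction fraction of pairs that are labeled positives
#'   (default 1/3).
#' @param ambiguous_fraction fraction of the *unlabeled* pool drawn from
#'   the overlap group (default 0.05, mirroring the low hidden-positive
#'   rate of sparse association matrices).
#' @param seed RNG seed.
#' @return list with `dataset` (a `pair_dataset`-shaped list: `X`,
#'   `label`) and `truth` (`"positive"`, `"negative"` or `"ambiguous"` per
#'   row).
#' @export
generate_pu_ground_truth <- function(n_pairs = 300L, separation = 4,
                                     dim = 16L, pos_fraction = 1 / 3,
                                     ambiguous_fraction = 0.05, seed = 1L) {
  if (separation < 0) stop("separation must be nonnegative")
  n_pos <- round(pos_fraction * n_pairs)
  n_unl <- n_pairs - n_pos
  n_amb <- round(ambiguous_fraction * n_unl)
  n_neg <- n_unl - n_amb
  with_seed(seed, {
    shift <- separation / (2 * sqrt(dim))  # ||mu_pos - mu_neg|| = separation
    mu_pos <- rep(shift, dim)
    draw <- function(k, mu) {
      matrix(stats::rnorm(k * dim), k, dim) + matrix(mu, k, dim, byrow = TRUE)
    }
    X <- rbind(
      draw(n_pos, mu_pos),
      draw(n_neg, -mu_pos),
      draw(n_amb, rep(0, dim))
    )
    truth <- c(rep("positive", n_pos), rep("negative", n_neg), rep("ambiguous", n_amb))
    label <- c(rep(1, n_pos), rep(NA_real_, n_neg + n_amb))
    perm <- sample.int(n_pairs)
    dataset <- structure(
      list(
        pairs = tibble::tibble(
          disease = NA_integer_, microbe = NA_integer_,
          disease_name = NA_character_, microbe_name = NA_character_
        )[rep(1L, n_pairs), ],
        X = X[perm, , drop = FALSE], label = label[perm]
      ),
      class = "pair_dataset"
    )
    list(dataset = dataset, truth = truth[perm])
  })
}

#' Precision of reliable-negative recovery against planted truth
#'
#' @param pu a `pu_result` from [run_pu()].
#' @param truth per-pair hidden truth from [generate_pu_ground_truth()].
#' @return fraction of reliable negatives whose hidden truth is
#'   `"negative"`; `NA` if none were selected.
#' @export
rn_precision <- function(pu, truth) {
  if (length(pu$rn) == 0L) return(NA_real_)
  mean(truth[pu$rn] == "negative")
}
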