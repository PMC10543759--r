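#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans plogis quantile rnorm runif sd
#' @importFrom utils read.table write.table head
#' @importFrom rlang .data
NULL

# Deterministic fan-out of one master seed into per-stage seeds.
# Kept below 2^31 so the result is always a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stage) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `expr` under a local RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Canonical entity-name key: trimmed, case-folded.
name_key <- function(x) tolower(trimws(x))

sigmoid <- function(x) stats::plogis(x)

# Numerically safe log(sigmoid(x)) = -log1p(exp(-x)).
log_sigmoid <- function(x) ifelse(x > -30, -log1p(exp(-x)), x)
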