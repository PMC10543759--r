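#' Bipartite microbe-disease association container
#'
#' Holds the binary association matrix `Y` (rows = diseases, columns =
#' microbes) together with the ordered entity names. `y[i, j] = 1` means
#' disease `i` has a recorded association with microbe `j`.
#'
#' @param disease_names character vector of unique disease names (length >= 2).
#' @param microbe_names character vector of unique microbe names (length >= 2).
#' @param Y binary matrix, `length(disease_names)` rows by
#'   `length(microbe_names)` columns, entries 0/1.
#'
#' @return An object of class `bipartite_associations`: a list with elements
#'   `disease_names`, `microbe_names` and `Y` (a named 0/1 matrix).
#' @export
#' @examples
#' y <- matrix(c(1, 1, 1, 0), nrow = 2, byrow = TRUE)
#' bipartite_associations(c("d1", "d2"), c("m1", "m2"), y)
bipartite_associations <- function(disease_names, microbe_names, Y) {
  disease_names <- as.character(disease_names)
  microbe_names <- as.character(microbe_names)
  Y <- as.matrix(Y)
  if (anyDuplicated(name_key(disease_names))) {
    stop("duplicate disease names after trimming/case-folding")
  }
  if (anyDuplicated(name_key(microbe_names))) {
    stop("duplicate microbe names after trimming/case-folding")
  }
  if (length(disease_names) < 2L || length(microbe_names) < 2L) {
    stop("need at least 2 diseases and 2 microbes")
  }
  if (nrow(Y) != length(disease_names) || ncol(Y) != length(microbe_names)) {
    stop("Y dimensions do not match name vectors")
  }
  if (!all(Y %in% c(0, 1))) stop("Y entries must be 0 or 1")
  storage.mode(Y) <- "double"
  dimnames(Y) <- list(disease_names, microbe_names)
  structure(
    list(disease_names = disease_names, microbe_names = microbe_names, Y = Y),
    class = "bipartite_associations"
  )
}

#' @export
print.bipartite_associations <- function(x, ...) {
  cat(sprintf(
    "<bipartite_associations> %d diseases x %d microbes, %d associations (density %.3f)\n",
    nrow(x$Y), ncol(x$Y), sum(x$Y), mean(x$Y)
  ))
  invisible(x)
}

#' Load a microbe-disease edge list
#'
#' Reads a two-column delimited file of (disease, microbe) pairs and builds
#' the binary association matrix. Duplicate pairs collapse to a single
#' association; row and column order follow first appearance in the file.
#' Lines starting with `#` are ignored. A header line is detected when
#' neither of its two fields re-appears in its own column further down.
#' Names are matched case-insensitively after trimming whitespace; the
#' first-seen spelling is kept for display.
#'
#' @param path path to the edge-list file.
#' @param dialect `"auto"` (default; tab if the first data line contains a
#'   tab, else comma), `"tsv"` or `"csv"`.
#'
#' @return A [bipartite_associations] object.
#' @export
#' @examples
#' edges <- system.file("extdata", "synthetic_edges_small.tsv", package = "mdalink")
#' load_associations(edges)
load_associations <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop("no associations")
  sep <- switch(dialect,
    tsv = "\t", csv = ",",
    auto = if (grepl("\t", lines[[1L]])) "\t" else ","
  )
  parts <- strsplit(lines, sep, fixed = TRUE)
  for (k in seq_along(parts)) {
    f <- trimws(parts[[k]])
    f <- f[nzchar(f)]
    if (length(f) < 2L) {
      stop(sprintf("line %d: expected a disease and a microbe field", line_no[[k]]))
    }
    parts[[k]] <- f[1:2]
  }
  d_raw <- vapply(parts, `[`, character(1L), 1L)
  m_raw <- vapply(parts, `[`, character(1L), 2L)
  # Header heuristic: first line is a header when neither field recurs below.
  if (length(d_raw) > 1L &&
      !(name_key(d_raw[[1L]]) %in% name_key(d_raw[-1L])) &&
      !(name_key(m_raw[[1L]]) %in% name_key(m_raw[-1L]))) {
    d_raw <- d_raw[-1L]
    m_raw <- m_raw[-1L]
  }
  if (length(d_raw) == 0L) stop("no associations")
  d_key <- name_key(d_raw)
  m_key <- name_key(m_raw)
  d_levels <- unique(d_key)
  m_levels <- unique(m_key)
  d_names <- trimws(d_raw)[match(d_levels, d_key)]
  m_names <- trimws(m_raw)[match(m_levels, m_key)]
  Y <- matrix(0, length(d_levels), length(m_levels))
  Y[cbind(match(d_key, d_levels), match(m_key, m_levels))] <- 1
  bipartite_associations(d_names, m_names, Y)
}

#' Write an edge list for a bipartite association object
#'
#' Inverse of [load_associations()]: one `disease<TAB>microbe` line per
#' association, in row-major matrix order, with a header line.
#'
#' @param assoc a [bipartite_associations] object.
#' @param path output file path.
#' @param sep field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path, sep = "\t") {
  stopifnot(inherits(assoc, "bipartite_associations"))
  idx <- which(assoc$Y == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  lines <- c(
    paste("disease", "microbe", sep = sep),
    paste(assoc$disease_names[idx[, 1L]], assoc$microbe_names[idx[, 2L]], sep = sep)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a named numeric matrix as delimited text
#'
#' Full-precision (17 significant digits) text round-trip: first row holds
#' column names, first column holds row names; fields containing the
#' delimiter are quoted. `read_matrix(write_matrix(M, f))` reproduces `M`
#' bit-identically.
#'
#' @param M numeric matrix with row and column names.
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns
#'   the named numeric matrix.
#' @export
write_matrix <- function(M, path, sep = "\t") {
  M <- as.matrix(M)
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    stop("matrix must have row and column names")
  }
  chr <- matrix(sprintf("%.17g", M), nrow(M), ncol(M), dimnames = dimnames(M))
  utils::write.table(chr, path,
    sep = sep, quote = TRUE, col.names = NA, row.names = TRUE
  )
  invisible(path)
}

#' @rdname write_matrix
#' @param square if `TRUE`, error unless the matrix read is square (used for
#'   similarity matrices).
#' @export
read_matrix <- function(path, sep = "\t", square = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path,
    sep = sep, header = TRUE, row.names = 1L,
    check.names = FALSE, quote = "\""
  )
  M <- as.matrix(df)
  storage.mode(M) <- "double"
  if (square && nrow(M) != ncol(M)) {
    stop(sprintf("expected a square matrix, got %d x %d", nrow(M), ncol(M)))
  }
  M
}
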