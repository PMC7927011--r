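#' @title Preprocessing chain: log2, quantile normalization, per-cell z-score
#'
#' @description The model consumes a real matrix `X` (genes x cells) in which
#' every cell (column) has zero mean and unit variance, so that `X'X` is (up
#' to the factor p) the cell-cell correlation matrix. The fixed chain is:
#' `log_transform()` -> `quantile_normalize()` -> `zscore_cells()`, applied
#' in that order by [preprocess_counts()]. Each step records itself in the
#' `provenance` attribute.
#'
#' @param counts an [count_matrix()] object.
#' @param min_cells optional gene filter: keep genes expressed (count > 0) in
#'   at least this many cells. Off (0) by default - the method is designed to
#'   run on the raw matrix with no feature selection.
#' @return A matrix of class `rggc_expr` with a `provenance` attribute.
#' @examples
#' sim <- simulate_counts(sim_design(n_cells = 30, n_genes = 200, seed = 1))
#' X <- preprocess_counts(sim$counts)
#' colMeans(X)[1:3]          # ~0
#' @name preprocess
NULL

expr_matrix <- function(X, provenance) {
  attr(X, "provenance") <- provenance
  class(X) <- c("rggc_expr", class(matrix()))
  X
}

#' @export
print.rggc_expr <- function(x, ...) {
  cat(sprintf("<rggc_expr> %d genes x %d cells [%s]\n", nrow(x), ncol(x),
              paste(attr(x, "provenance"), collapse = " -> ")))
  invisible(x)
}

#' @rdname preprocess
#' @export
preprocess_counts <- function(counts, min_cells = 0) {
  stopifnot(inherits(counts, "rggc_counts"))
  if (min_cells > 0) {
    keep <- rowSums(counts > 0) >= min_cells
    counts <- count_matrix(unclass(counts)[keep, , drop = FALSE])
  }
  zscore_cells(quantile_normalize(log_transform(counts)))
}

#' @rdname preprocess
#' @export
log_transform <- function(counts) {
  stopifnot(inherits(counts, "rggc_counts") || is.matrix(counts))
  expr_matrix(log2(unclass(counts) + 1), "log2(x+1)")
}

#' Quantile-normalize cells to a common distribution
#'
#' Equalizes sequencing depth by forcing every cell's value distribution onto
#' the reference distribution (the mean across cells of the sorted columns).
#' Tied values within a cell - ubiquitous in log-counts, where most entries
#' are zero - all receive the mean reference value over their rank span
#' (e.g. z zeros occupying ranks 1..z all get `mean(ref[1:z])`), so the
#' result does not depend on gene order. A constant cell maps entirely to
#' the overall reference mean (with a warning).
#'
#' @param X an `rggc_expr` (or plain) matrix, genes x cells, `p >= 2`.
#' @return `rggc_expr` matrix; every column has the same sorted values.
#' @export
quantile_normalize <- function(X) {
  if (nrow(X) < 2) stop("quantile normalization needs at least 2 genes")
  prov <- attr(X, "provenance")
  if (any(apply(X, 2, function(col) max(col) == min(col))))
    warning("constant column(s): every value mapped to the reference mean")
  ref <- rowMeans(apply(unclass(X), 2, sort, method = "quick"))
  cs <- c(0, cumsum(ref))
  Y <- apply(unclass(X), 2, function(col) {
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  })
  dimnames(Y) <- dimnames(X)
  expr_matrix(Y, c(prov, "quantile"))
}

#' Standardize each cell to zero mean and unit variance
#'
#' Column-wise z-score with the population standard deviation (divide by p,
#' not p-1); the convention only rescales `X'X` by a constant, which cancels
#' in the normalized adjacency, and makes the chain deterministic about its
#' own output scale. Zero-variance cells carry no signal and are set to all
#' zeros with a warning; their ids are recorded in the `degenerate_cells`
#' attribute.
#'
#' @param X an `rggc_expr` (or plain) matrix, genes x cells, `p >= 2`.
#' @return `rggc_expr` matrix with standardized columns.
#' @export
zscore_cells <- function(X) {
  if (nrow(X) < 2) stop("z-scoring needs at least 2 genes")
  prov <- attr(X, "provenance")
  p <- nrow(X)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(X^2) - mu^2)  # population sd
  degenerate <- sdv < 1e-12
  sdv[degenerate] <- 1
  Y <- sweep(sweep(unclass(X), 2, mu, "-"), 2, sdv, "/")
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance cell(s) set to all zeros")
    Y[, degenerate] <- 0
  }
  Y <- expr_matrix(Y, c(prov, "zscore"))
  attr(Y, "degenerate_cells") <- colnames(X)[degenerate]
  Y
}
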