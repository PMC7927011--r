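#' Default regularization strength
#'
#' The ridge penalty `lambda` is the model's only parameter and does not need
#' tuning: set it from an information-criterion analogy, `lambda = 2` (AIC)
#' or `lambda = ln p` (BIC, the default with p genes), and the clustering is
#' stable over several orders of magnitude of `lambda` because Louvain reacts
#' to the relative, not absolute, edge weights.
#'
#' @param p number of genes (needed for `"bic"`).
#' @param criterion `"bic"` (ln p), `"aic"` (2), or `"custom"`.
#' @param value the value to use with `criterion = "custom"`; must be >= 0.
#' @return The numeric lambda.
#' @examples
#' default_lambda(criterion = "aic")      # 2
#' default_lambda(5000)                   # log(5000)
#' @export
default_lambda <- function(p = NULL, criterion = c("bic", "aic", "custom"),
                           value = NULL) {
  criterion <- match.arg(criterion)
  switch(criterion,
    aic = 2,
    bic = {
      if (is.null(p) || p < 2) stop("BIC lambda needs the gene count p >= 2")
      log(p)
    },
    custom = {
      if (is.null(value)) stop("criterion = 'custom' needs `value`")
      if (!is.numeric(value) || length(value) != 1 || value < 0)
        stop("custom lambda must be a single nonnegative number")
      as.numeric(value)
    })
}

#' Inverse regularized Gram matrix S = (X'X + lambda I)^-1
#'
#' The closed-form core: solving all n ridge self-representation problems at
#' once reduces to one symmetric positive-definite inverse of the n x n
#' regularized Gram matrix, computed by Cholesky factorization (never by
#' per-cell regressions, and never elementwise).
#'
#' @param X preprocessed expression matrix, genes x cells.
#' @param lambda ridge penalty, >= 0. With `lambda = 0` the Gram matrix must
#'   be numerically nonsingular (it cannot be when n > p); a positive lambda
#'   guarantees the inverse exists.
#' @return Symmetric n x n matrix `S`.
#' @export
compute_S <- function(X, lambda) {
  stopifnot(is.matrix(X), is.numeric(lambda), length(lambda) == 1, lambda >= 0)
  n <- ncol(X)
  A <- crossprod(X)
  diag(A) <- diag(A) + lambda
  ch <- tryCatch(chol(A), error = function(e) {
    if (lambda == 0)
      stop("X'X is singular with lambda = 0 (always so when cells > genes); ",
           "use a positive lambda to guarantee the inverse exists",
           call. = FALSE)
    stop("X'X + lambda*I is not positive definite: ", conditionMessage(e),
         call. = FALSE)
  })
  S <- chol2inv(ch)
  S <- (S + t(S)) / 2
  if (!is.null(colnames(X)))
    dimnames(S) <- list(colnames(X), colnames(X))
  S
}

#' Cell-cell adjacency from the regularized Gaussian graphical model
#'
#' Converts `S = (X'X + lambda I)^-1` into the high-order partial-correlation
#' adjacency `W`. Off-diagonal entries, by normalization mode:
#' \describe{
#'   \item{`none`}{`w_ij = -lambda * s_ij` (the raw closed form `W = I -
#'     lambda S` with the diagonal dropped).}
#'   \item{`column`}{`w_ij = -s_ij / s_jj`.}
#'   \item{`symmetric`}{`w_ij = -s_ij / sqrt(s_ii s_jj)`, the standard map
#'     from an inverse covariance to partial correlations; default.}
#' }
#' The diagonal is always 0. `symmetrize` averages `W` with its transpose
#' (needed for `column` mode, where `W` is not symmetric; on by default).
#' By default negative partial correlations are retained and handled by
#' signed modularity downstream; set `clip_negative = TRUE` to zero them so
#' the graph suits standard (nonnegative) modularity.
#'
#' @param S symmetric positive-definite matrix from [compute_S()].
#' @param lambda the penalty used to build `S` (enters the `none` scaling and
#'   is recorded in the model).
#' @param normalization `"symmetric"`, `"column"` or `"none"`.
#' @param symmetrize average with the transpose.
#' @param clip_negative zero out negative weights.
#' @return An object of class `rggc_graph`: list with elements `W`, `S`,
#'   `lambda`, `normalization`, `symmetrized`, `clipped`, `cell_ids`.
#' @export
compute_W <- function(S, lambda,
                      normalization = c("symmetric", "column", "none"),
                      symmetrize = TRUE, clip_negative = FALSE) {
  normalization <- match.arg(normalization)
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  d <- diag(S)
  if (any(d < 1e-12))
    stop("numerical error: diag(S) has entries below 1e-12; ",
         "S is not positive definite")
  W <- switch(normalization,
    none = -lambda * S,
    column = -sweep(S, 2, d, "/"),
    symmetric = { r <- 1 / sqrt(d); -(r %o% r) * S })
  diag(W) <- 0
  if (symmetrize) W <- (W + t(W)) / 2
  if (clip_negative) W[W < 0] <- 0
  dimnames(W) <- dimnames(S)
  structure(list(W = W, S = S, lambda = lambda,
                 normalization = normalization,
                 symmetrized = symmetrize, clipped = clip_negative,
                 cell_ids = colnames(S)),
            class = "rggc_graph")
}

#' Fit the cell-cell graph in one call
#'
#' Convenience wrapper: [compute_S()] then [compute_W()], with lambda taken
#' from [default_lambda()] when given as a criterion name.
#'
#' @param X preprocessed expression matrix (genes x cells).
#' @param lambda a number, or `"bic"` / `"aic"`.
#' @inheritParams compute_W
#' @return An `rggc_graph` object.
#' @export
fit_graph <- function(X, lambda = "bic",
                      normalization = c("symmetric", "column", "none"),
                      symmetrize = TRUE, clip_negative = FALSE) {
  if (is.character(lambda))
    lambda <- default_lambda(nrow(X), match.arg(lambda, c("bic", "aic")))
  compute_W(compute_S(X, lambda), lambda, match.arg(normalization),
            symmetrize, clip_negative)
}

#' @export
print.rggc_graph <- function(x, ...) {
  cat(sprintf(
    "<rggc_graph> %d cells, lambda = %.4g, normalization = %s%s%s\n",
    nrow(x$W), x$lambda, x$normalization,
    if (x$symmetrized) ", symmetrized" else "",
    if (x$clipped) ", clipped" else ""))
  invisible(x)
}

#' Edge list of a fitted graph
#'
#' @param x an `rggc_graph`.
#' @param ... unused.
#' @return Tibble with one row per unordered cell pair with nonzero weight:
#'   `from`, `to`, `weight`.
#' @export
tidy.rggc_graph <- function(x, ...) {
  W <- x$W
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  tibble::tibble(from = x$cell_ids[idx[, 1]],
                 to = x$cell_ids[idx[, 2]],
                 weight = W[idx])
}

#' @rdname tidy.rggc_graph
#' @return `glance()`: one-row tibble with `n_cells`, `lambda`,
#'   `normalization`, `n_edges`, `mean_weight`.
#' @export
glance.rggc_graph <- function(x, ...) {
  up <- x$W[upper.tri(x$W)]
  tibble::tibble(n_cells = nrow(x$W), lambda = x$lambda,
                 normalization = x$normalization,
                 n_edges = sum(up != 0), mean_weight = mean(up))
}

#' Brute-force constrained ridge solver (validation oracle)
#'
#' Solves one column's self-representation problem directly - minimize
#' `||x_j - X w||^2 + lambda ||w||^2` subject to `w_j = 0` - by deleting
#' column j, solving the reduced ridge system, and reinserting the zero.
#' This is the slow per-cell route the closed form replaces; it exists to
#' validate `compute_W`'s edge structure and the L2 grouping effect, not for
#' production use.
#'
#' @param X expression matrix, genes x cells.
#' @param lambda ridge penalty, > 0.
#' @param j column (cell) index.
#' @return Numeric coefficient vector of length n with `[j] = 0`.
#' @export
ridge_oracle <- function(X, lambda, j) {
  stopifnot(lambda > 0, j >= 1, j <= ncol(X))
  Xm <- X[, -j, drop = FALSE]
  A <- crossprod(Xm)
  diag(A) <- diag(A) + lambda
  w <- solve(A, crossprod(Xm, X[, j, drop = FALSE]))
  out <- numeric(ncol(X))
  out[-j] <- w
  out
}
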