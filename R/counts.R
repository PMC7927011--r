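#' Construct a validated count matrix
#'
#' The raw-data container of the package: a nonnegative integer matrix with
#' genes in rows and cells in columns, carrying unique gene and cell
#' identifiers as dimnames. All readers and the simulator return this class;
#' the preprocessing chain consumes it.
#'
#' @param counts numeric matrix, genes x cells, all entries nonnegative
#'   integers (integer storage not required; values must be whole numbers).
#' @param gene_ids,cell_ids character vectors of unique identifiers. Defaults
#'   to existing dimnames, or `g1..gp` / `c1..cn` synthesized when absent so
#'   downstream outputs are always joinable.
#' @return A matrix of class `rggc_counts` with dimnames set.
#' @examples
#' m <- count_matrix(matrix(0:5, nrow = 3))
#' dim(m)
#' @export
count_matrix <- function(counts, gene_ids = NULL, cell_ids = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (genes x cells)")
  if (anyNA(counts))
    stop("validation error: count matrix contains missing values")
  if (any(counts < 0))
    stop("validation error: count matrix contains negative entries")
  if (any(counts != floor(counts)))
    stop("validation error: count matrix contains non-integer entries")
  p <- nrow(counts); n <- ncol(counts)
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(cell_ids)) cell_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(n))
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != p)
    stop("validation error: ", length(gene_ids), " gene ids for ", p, " rows")
  if (length(cell_ids) != n)
    stop("validation error: ", length(cell_ids), " cell ids for ", n, " columns")
  if (anyDuplicated(gene_ids))
    stop("validation error: duplicated gene ids")
  if (anyDuplicated(cell_ids))
    stop("validation error: duplicated cell ids")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(gene_ids, cell_ids)
  class(counts) <- c("rggc_counts", class(matrix()))
  counts
}

#' @export
print.rggc_counts <- function(x, ...) {
  cat(sprintf("<rggc_counts> %d genes x %d cells, %.1f%% zeros\n",
              nrow(x), ncol(x), 100 * mean(x == 0)))
  invisible(x)
}

gene_ids <- function(x) rownames(x)
cell_ids <- function(x) colnames(x)

#' Turn a count matrix into a long tibble
#'
#' One row per nonzero entry: `gene`, `cell`, `count`. Mostly useful for
#' plotting and spot checks; the pipeline itself works on the matrix.
#'
#' @param x an `rggc_counts` matrix.
#' @param ... unused.
#' @return A tibble with columns `gene`, `cell`, `count`.
#' @export
tidy.rggc_counts <- function(x, ...) {
  idx <- which(x != 0, arr.ind = TRUE)
  tibble::tibble(gene = rownames(x)[idx[, 1]],
                 cell = colnames(x)[idx[, 2]],
                 count = as.numeric(x[idx]))
}
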