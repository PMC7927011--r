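#' Read a genes-by-cells count matrix
#'
#' Reads MatrixMarket coordinate files (with optional `genes.tsv` /
#' `features.tsv` and `barcodes.tsv` sidecars next to the `.mtx` file) or
#' dense CSV/TSV with a header row of cell ids and gene ids in the first
#' column. Orientation is genes x cells everywhere in the package; use
#' `transpose = TRUE` for cells-x-genes inputs.
#'
#' When a dense file has no id row/column at all, identifiers are synthesized
#' and, because the orientation is then ambiguous, the longer axis is treated
#' as genes (scRNA-seq matrices have far more genes than cells) with a
#' warning.
#'
#' @param path path to a `.mtx`, `.csv` or `.tsv`/`.txt` file, or a directory
#'   containing `matrix.mtx`.
#' @param format one of `"auto"` (by extension), `"mtx"`, `"csv"`, `"tsv"`.
#' @param transpose flip a cells-x-genes input to the internal genes-x-cells
#'   orientation.
#' @return An [count_matrix()] object.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' m <- count_matrix(matrix(rpois(12, 2), 4, 3))
#' write_counts(m, dir)
#' m2 <- read_counts(file.path(dir, "matrix.mtx"))
#' all.equal(unclass(m), unclass(m2), check.attributes = FALSE)
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx))
      stop("directory ", path, " has no matrix.mtx")
    path <- mtx
    format <- "mtx"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
      stop("cannot infer format from extension '.", ext,
           "'; pass format= explicitly"))
  }
  m <- if (format == "mtx") read_counts_mtx(path) else
    read_counts_dense(path, sep = if (format == "csv") "," else "\t")
  if (transpose) m <- t(m)
  count_matrix(m)
}

read_counts_mtx <- function(path) {
  m <- tryCatch(as.matrix(Matrix::readMM(path)),
                error = function(e) stop("parse error in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  dir <- dirname(path)
  sidecar <- function(cands) {
    for (f in file.path(dir, cands)) if (file.exists(f)) return(f)
    NULL
  }
  gf <- sidecar(c("genes.tsv", "features.tsv"))
  bf <- sidecar("barcodes.tsv")
  if (!is.null(gf)) {
    g <- read.table(gf, sep = "\t", header = FALSE,
                    colClasses = "character")[[1]]
    if (length(g) != nrow(m))
      stop("validation error: ", basename(gf), " has ", length(g),
           " ids for ", nrow(m), " matrix rows")
    rownames(m) <- g
  }
  if (!is.null(bf)) {
    b <- read.table(bf, sep = "\t", header = FALSE,
                    colClasses = "character")[[1]]
    if (length(b) != ncol(m))
      stop("validation error: ", basename(bf), " has ", length(b),
           " ids for ", ncol(m), " matrix columns")
    colnames(m) <- b
  }
  m
}

read_counts_dense <- function(path, sep) {
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  suppressWarnings(num <- as.numeric(first))
  has_header <- anyNA(num)
  if (has_header) {
    df <- tryCatch(
      read.table(path, sep = sep, header = TRUE, row.names = 1,
                 check.names = FALSE),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    as.matrix(df)
  } else {
    m <- as.matrix(read.table(path, sep = sep, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) < ncol(m)) {
      warning("no identifiers in ", basename(path),
              "; orientation ambiguous - treating the longer axis (",
              ncol(m), ") as genes")
      m <- t(m)
    }
    m
  }
}

#' Write a count matrix to disk
#'
#' `mtx` writes MatrixMarket `matrix.mtx` plus `genes.tsv` and `barcodes.tsv`
#' sidecars into a directory (the layout [read_counts()] and the CLI expect);
#' `csv`/`tsv` write a dense table with cell-id header and gene-id column.
#'
#' @param x an `rggc_counts` matrix.
#' @param path output directory for `mtx`, output file otherwise.
#' @param format `"mtx"`, `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(x), file.path(path, "genes.tsv"))
    writeLines(colnames(x), file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read cell labels
#'
#' Accepts one label per line, or a two-column `(cell_id, label)` table with
#' header. With `cell_ids` given (e.g. from an accompanying count matrix),
#' two-column files are realigned to that order and one-column files are
#' length-checked against it.
#'
#' @param path label file.
#' @param cell_ids optional character vector of cell identifiers to align to.
#' @return A character vector of labels, named by cell id when ids are known.
#' @export
read_labels <- function(path, cell_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  two_col <- grepl("\t", first) || grepl(",", first)
  if (two_col) {
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- read.table(path, sep = sep, header = TRUE, colClasses = "character")
    if (ncol(df) < 2)
      stop("parse error in ", path, ": expected two columns (cell_id, label)")
    labs <- stats::setNames(df[[2]], df[[1]])
    if (!is.null(cell_ids)) {
      missing <- setdiff(cell_ids, names(labs))
      if (length(missing))
        stop("validation error: label file lacks cell ids: ",
             paste(head(missing, 5), collapse = ", "),
             if (length(missing) > 5) ", ...")
      labs <- labs[cell_ids]
    }
  } else {
    labs <- readLines(path)
    labs <- labs[nzchar(labs)]
    if (!is.null(cell_ids)) {
      if (length(labs) != length(cell_ids))
        stop("validation error: ", length(labs), " labels for ",
             length(cell_ids), " cells")
      names(labs) <- cell_ids
    }
  }
  labs
}

#' Write clustering results
#'
#' Writes `clusters.tsv` (columns `cell_id`, `cluster`), a JSON run summary
#' `summary.json` (lambda, modularity Q, number of clusters, restarts, seed,
#' normalization, n cells) and, when an embedding is supplied,
#' `embedding.tsv` with the 2-D coordinates.
#'
#' @param partition an [louvain_cluster()] result.
#' @param path output directory (created if needed).
#' @param coords optional [embed_cells()] result or any n x 2 coordinate
#'   table aligned to the partition's cells.
#' @return `path`, invisibly.
#' @export
write_results <- function(partition, path, coords = NULL) {
  stopifnot(inherits(partition, "rggc_partition"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  write.table(tidy(partition), file.path(path, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    lambda = partition$lambda,
    Q = partition$Q,
    n_clusters = partition$n_clusters,
    restarts = partition$restarts_used,
    seed = partition$seed,
    mode = partition$mode,
    normalization = partition$normalization,
    n_cells = length(partition$labels))
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       file.path(path, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(coords) && NROW(coords) > 0) {
    cdf <- as.data.frame(coords)
    write.table(cdf, file.path(path, "embedding.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
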