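#' Cluster a count matrix end to end
#'
#' The one-call pipeline: preprocess (log2, quantile normalization, per-cell
#' z-score), fit the regularized self-representation graph, and partition it
#' with multi-restart Louvain. No argument needs to be set: `lambda`
#' defaults to the BIC-style `ln p`, the adjacency is the symmetric
#' partial-correlation normalization with negative correlations retained
#' and handled by signed modularity, and the number of clusters emerges
#' from modularity maximization. `mode = "standard"` clips negative weights
#' (unless `clip_negative` says otherwise) and runs plain Louvain.
#'
#' @param counts an [count_matrix()] (or a plain nonnegative integer matrix,
#'   genes x cells).
#' @param lambda a number, or `"bic"` (ln p, default) / `"aic"` (2).
#' @inheritParams compute_W
#' @inheritParams louvain_cluster
#' @param min_cells optional gene filter (see [preprocess_counts()]).
#' @return An object of class `rggc_fit`: list with `partition`
#'   (`rggc_partition`), `graph` (`rggc_graph`) and `n_genes_used`.
#' @examples
#' sim <- simulate_counts(sim_design(n_cells = 60, n_genes = 400,
#'                                   de_prob = 1, seed = 2))
#' fit <- rggc_cluster(sim$counts, restarts = 2)
#' glance(fit)
#' nmi(sim$labels, fit$partition$labels)
#' @export
rggc_cluster <- function(counts, lambda = "bic",
                         normalization = c("symmetric", "column", "none"),
                         mode = c("signed", "standard"),
                         clip_negative = NULL,
                         restarts = 10, seed = 0, min_cells = 0) {
  if (!inherits(counts, "rggc_counts")) counts <- count_matrix(counts)
  mode <- match.arg(mode)
  if (is.null(clip_negative)) clip_negative <- mode == "standard"
  X <- preprocess_counts(counts, min_cells = min_cells)
  graph <- fit_graph(X, lambda = lambda,
                     normalization = match.arg(normalization),
                     clip_negative = clip_negative)
  partition <- louvain_cluster(graph, restarts = restarts, seed = seed,
                               mode = mode)
  structure(list(partition = partition, graph = graph,
                 n_genes_used = nrow(X)),
            class = "rggc_fit")
}

#' @export
print.rggc_fit <- function(x, ...) {
  print(x$graph); print(x$partition)
  invisible(x)
}

#' Tidy / glance methods for a full pipeline fit
#'
#' @param x an `rggc_fit` from [rggc_cluster()].
#' @param ... unused.
#' @return `tidy()`: the per-cell cluster tibble; `glance()`: a one-row fit
#'   summary (n cells, clusters, Q, lambda, normalization, genes used).
#' @export
tidy.rggc_fit <- function(x, ...) tidy(x$partition)

#' @rdname tidy.rggc_fit
#' @export
glance.rggc_fit <- function(x, ...) {
  out <- glance(x$partition)
  out$normalization <- x$graph$normalization
  out$n_genes <- x$n_genes_used
  out
}

#' @rdname plot_adjacency
#' @export
autoplot.rggc_fit <- function(object, ...)
  plot_adjacency(object$graph, object$partition)

#' Run the clustering pipeline from a config (CLI backend)
#'
#' Thin, file-oriented wrapper over [rggc_cluster()]: reads the counts,
#' runs the pipeline, writes `clusters.tsv` + `summary.json` (and
#' `embedding.tsv` when `viz = TRUE`) into `out`, logging one line per
#' stage. All config entries are optional except `input`.
#'
#' @param config named list: `input` (path, directory, or an
#'   `rggc_counts`), `out` (output directory; omit to skip writing),
#'   `format`, `transpose`, `lambda` (number or "bic"/"aic"),
#'   `normalization`, `clip_negative`, `mode`, `restarts`, `seed`,
#'   `min_cells`, `viz`, `viz_seed`.
#' @return The `rggc_fit`, invisibly.
#' @export
run_cluster <- function(config) {
  cfg <- modifyList(list(format = "auto", transpose = FALSE, lambda = "bic",
                         normalization = "symmetric", clip_negative = NULL,
                         mode = "signed", restarts = 10, seed = 0,
                         min_cells = 0, viz = FALSE, viz_seed = 0),
                    config)
  if (is.null(cfg$input)) stop("config needs `input`")
  counts <- if (inherits(cfg$input, "rggc_counts")) cfg$input
            else read_counts(cfg$input, format = cfg$format,
                             transpose = cfg$transpose)
  message(sprintf("[io] %d genes x %d cells", nrow(counts), ncol(counts)))
  t0 <- proc.time()[3]
  fit <- rggc_cluster(counts, lambda = cfg$lambda,
                      normalization = cfg$normalization,
                      clip_negative = cfg$clip_negative, mode = cfg$mode,
                      restarts = cfg$restarts, seed = cfg$seed,
                      min_cells = cfg$min_cells)
  message(sprintf(
    "[cluster] lambda = %.4g, Q = %.4f, %d clusters (%.1f s)",
    fit$graph$lambda, fit$partition$Q, fit$partition$n_clusters,
    proc.time()[3] - t0))
  coords <- NULL
  if (isTRUE(cfg$viz)) {
    coords <- embed_cells(fit$graph, seed = cfg$viz_seed)
    message("[viz] t-SNE embedding computed")
  }
  if (!is.null(cfg$out)) {
    write_results(fit$partition, cfg$out, coords = coords)
    message("[io] results written to ", cfg$out)
  }
  invisible(fit)
}

#' Evaluate detected clusters against reference labels (CLI backend)
#'
#' @param truth,pred label files (see [read_labels()]) or label vectors.
#' @param out optional path for a JSON report.
#' @return List with `nmi`, `ari`, `n` (cells), `s` (truth classes), `r`
#'   (detected classes).
#' @export
run_evaluate <- function(truth, pred, out = NULL) {
  if (is.character(truth) && length(truth) == 1 && file.exists(truth))
    truth <- read_labels(truth)
  if (is.character(pred) && length(pred) == 1 && file.exists(pred))
    pred <- read_labels(pred)
  if (!is.null(names(truth)) && !is.null(names(pred))) {
    missing <- setdiff(names(truth), names(pred))
    if (length(missing))
      stop("validation error: predictions lack cell ids: ",
           paste(head(missing, 5), collapse = ", "))
    pred <- pred[names(truth)]
  }
  res <- list(nmi = nmi(truth, pred), ari = ari(truth, pred),
              n = length(truth),
              s = length(unique(truth)), r = length(unique(pred)))
  if (!is.null(out))
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
  res
}

#' Simulate counts to disk (CLI backend)
#'
#' @param preset `"simdata1"`, `"simdata2"`, `"simdata3"`, or a
#'   [sim_design()].
#' @param seed RNG seed.
#' @param out output directory: writes `matrix.mtx` + sidecars and a
#'   two-column `labels.tsv`.
#' @return The simulation list, invisibly.
#' @export
run_simulate <- function(preset, seed = 1, out = NULL) {
  design <- if (inherits(preset, "sim_design")) preset
            else sim_presets()[[match.arg(preset, names(sim_presets()))]]
  sim <- simulate_counts(design, seed = seed)
  if (!is.null(out)) {
    write_counts(sim$counts, out)
    write.table(data.frame(cell_id = names(sim$labels),
                           label = unname(sim$labels)),
                file.path(out, "labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    message("[simulate] ", out, ": ", nrow(sim$counts), " genes x ",
            ncol(sim$counts), " cells, ", design$n_groups, " groups")
  }
  invisible(sim)
}
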