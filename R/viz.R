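#' 2-D t-SNE embedding of cells from the fitted similarity matrix
#'
#' Embeds cells for visualization using the model's own high-order
#' correlation matrix, not the expression matrix: the symmetrized, clipped
#' `W` is min-max scaled to `[0, 1]` and converted to the dissimilarity
#' `d_ij = 1 - w_ij` (`d_ii = 0`), on which an exact (O(n^2)) t-SNE with
#' precomputed distances is run. Because t-SNE preserves only local
#' neighborhoods, distances *between* clusters in the embedding carry no
#' meaning. The embedding is strictly downstream of clustering and never
#' feeds back into it.
#'
#' @param model an `rggc_graph`, or a bare symmetric similarity matrix.
#' @param seed RNG seed for the embedding initialization.
#' @param perplexity t-SNE perplexity; capped at `(n - 1) / 3`.
#' @param n_iter gradient-descent iterations.
#' @return A tibble of class `rggc_embedding` with columns `cell_id`,
#'   `tsne1`, `tsne2` and attributes `method`, `perplexity`, `seed`.
#' @export
embed_cells <- function(model, seed = 0, perplexity = 30, n_iter = 500) {
  W <- if (inherits(model, "rggc_graph")) model$W else model
  n <- nrow(W)
  if (n < 5) stop("embedding needs at least 5 cells")
  W <- (W + t(W)) / 2
  W[W < 0] <- 0
  diag(W) <- 0
  rng <- range(W[upper.tri(W)])
  Wt <- if (rng[2] > rng[1]) (W - rng[1]) / (rng[2] - rng[1])
        else matrix(0, n, n)
  D <- 1 - Wt
  diag(D) <- 0
  perplexity <- min(perplexity, (n - 1) / 3)
  Y <- withr::with_seed(seed, tsne_precomputed(D, perplexity, n_iter))
  ids <- colnames(W)
  if (is.null(ids)) ids <- paste0("c", seq_len(n))
  out <- tibble::tibble(cell_id = ids, tsne1 = Y[, 1], tsne2 = Y[, 2])
  attr(out, "method") <- "tsne(precomputed)"
  attr(out, "perplexity") <- perplexity
  attr(out, "seed") <- seed
  class(out) <- c("rggc_embedding", class(out))
  out
}

# Exact t-SNE on a precomputed distance matrix: per-point precision by
# bisection to the target perplexity, then momentum gradient descent with
# early exaggeration. O(n^2) memory/time; fine for the <= few-thousand cells
# this package targets.
tsne_precomputed <- function(D, perplexity, n_iter) {
  n <- nrow(D)
  D2 <- D^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      e <- exp(-di * beta)
      sumE <- sum(e)
      if (sumE == 0) { H <- 0; pr <- e } else {
        pr <- e / sumE
        H <- log(sumE) + beta * sum(di * e) / sumE
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else { betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- pr
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 100) P * 4 else P       # early exaggeration
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 100) 0.5 else 0.8
    inc <- momentum * inc - 200 * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y), "-")
  }
  Y
}

#' Cell ordering for a clustered heatmap
#'
#' Orders cells by cluster, then within each cluster by total connection
#' weight (strongest hubs first), so that a well-clustered `W` shows a
#' block-diagonal checkerboard when plotted with the same permutation on
#' rows and columns.
#'
#' @param model an `rggc_graph` or adjacency matrix.
#' @param partition an `rggc_partition` (or bare label vector).
#' @return Integer permutation of the cells.
#' @export
heatmap_order <- function(model, partition) {
  W <- if (inherits(model, "rggc_graph")) model$W else model
  labels <- if (inherits(partition, "rggc_partition")) partition$labels
            else partition
  stopifnot(length(labels) == nrow(W))
  strength <- vapply(seq_len(nrow(W)), function(i)
    sum(W[i, labels == labels[i]]), numeric(1))
  order(labels, -strength)
}

#' Plot the adjacency matrix as an ordered heatmap
#'
#' @param model an `rggc_graph`.
#' @param partition optional `rggc_partition` used to order cells into
#'   blocks; without it cells keep their input order.
#' @return A ggplot object.
#' @export
plot_adjacency <- function(model, partition = NULL) {
  W <- model$W
  ord <- if (is.null(partition)) seq_len(nrow(W))
         else heatmap_order(model, partition)
  Wo <- W[ord, ord]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(Wo)), times = ncol(Wo)),
    col = rep(seq_len(ncol(Wo)), each = nrow(Wo)),
    weight = as.vector(Wo))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "cell (ordered)", y = "cell (ordered)",
                  fill = "w") +
    ggplot2::theme_minimal()
}

#' @rdname plot_adjacency
#' @param object an `rggc_graph` (for `autoplot`).
#' @param ... passed on to `plot_adjacency()`.
#' @export
autoplot.rggc_graph <- function(object, ...) plot_adjacency(object, ...)

#' Plot a 2-D embedding colored by cluster
#'
#' @param object an `rggc_embedding` from [embed_cells()].
#' @param labels optional cluster labels: an `rggc_partition` or a vector
#'   aligned to the embedding's cells.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rggc_embedding <- function(object, labels = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (inherits(labels, "rggc_partition"))
    labels <- labels$labels[df$cell_id]
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$tsne1, y = .data$tsne2))
  } else {
    df$cluster <- factor(labels)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$tsne1, y = .data$tsne2,
                                     color = .data$cluster))
  }
  p + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
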