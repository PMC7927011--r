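#' Specify a splatter-style simulation design
#'
#' Describes a gamma-Poisson scRNA-seq count simulation with group structure:
#' baseline gene means are Gamma draws, each group marks a random subset of
#' genes as differentially expressed with log-normal fold factors (halved
#' between up and down), cells get log-normal library sizes, expression is
#' over-dispersed with a biological coefficient of variation (BCV), counts
#' are Poisson, and an optional logistic dropout zeroes low-expression
#' entries. This is the generative skeleton of the splatter simulator,
#' re-expressed compactly; it is an emulation of that model's structure, not
#' a byte-level clone.
#'
#' Defaults follow the conventional splatter parameterization:
#' `mean_shape = 0.6`, `mean_rate = 0.3` (baseline means around 2),
#' `de_fac_loc = 0.1`, `de_fac_scale = 0.4` (DE fold factors mostly in
#' 0.6-1.7x), `lib_loc = 11`, `lib_scale = 0.2` (libraries around 60k
#' reads), `bcv = 0.18`. Dropout is off unless `dropout_mid` is set; the
#' logistic midpoint is on the `log(expected expression + 1)` scale with
#' slope `dropout_shape` (zeroing probability
#' `1 / (1 + exp(dropout_shape * (log(lambda + 1) - dropout_mid)))`,
#' decreasing in expression).
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param group_prob relative group abundances; must sum to 1. Its length
#'   sets the number of groups.
#' @param de_prob per-group probability that a gene is differentially
#'   expressed (recycled to the number of groups).
#' @param de_fac_loc,de_fac_scale log-normal meanlog/sdlog of DE fold
#'   factors.
#' @param mean_shape,mean_rate Gamma parameters of baseline gene means.
#' @param lib_loc,lib_scale log-normal meanlog/sdlog of per-cell library
#'   sizes (expected total counts).
#' @param bcv biological coefficient of variation of the over-dispersion.
#' @param dropout_mid logistic dropout midpoint, or `NA` to disable dropout.
#' @param dropout_shape logistic dropout slope (> 0).
#' @param seed default RNG seed used by [simulate_counts()].
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_cells = 600, n_genes = 5000,
                       group_prob = rep(0.25, 4),
                       de_prob = 0.1,
                       de_fac_loc = 0.1, de_fac_scale = 0.4,
                       mean_shape = 0.6, mean_rate = 0.3,
                       lib_loc = 11, lib_scale = 0.2,
                       bcv = 0.18,
                       dropout_mid = NA, dropout_shape = 1,
                       seed = 1) {
  n_groups <- length(group_prob)
  de_prob <- rep_len(de_prob, n_groups)
  design <- structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         n_groups = n_groups, group_prob = group_prob, de_prob = de_prob,
         de_fac_loc = de_fac_loc, de_fac_scale = de_fac_scale,
         mean_shape = mean_shape, mean_rate = mean_rate,
         lib_loc = lib_loc, lib_scale = lib_scale, bcv = bcv,
         dropout_mid = dropout_mid, dropout_shape = dropout_shape,
         seed = as.integer(seed)),
    class = "sim_design")
  validate_design(design)
  design
}

validate_design <- function(d) {
  if (d$n_cells < 2 || d$n_genes < 2)
    stop("validation error: need at least 2 cells and 2 genes")
  if (abs(sum(d$group_prob) - 1) > 1e-9)
    stop("validation error: group_prob must sum to 1 (got ",
         sum(d$group_prob), ")")
  if (any(d$group_prob <= 0))
    stop("validation error: group_prob entries must be positive")
  if (length(d$de_prob) != d$n_groups)
    stop("validation error: de_prob length must match the number of groups")
  if (any(d$de_prob < 0 | d$de_prob > 1))
    stop("validation error: de_prob entries must lie in [0, 1]")
  for (nm in c("de_fac_scale", "mean_shape", "mean_rate", "lib_scale",
               "bcv", "dropout_shape"))
    if (d[[nm]] <= 0)
      stop("validation error: ", nm, " must be positive")
  invisible(d)
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "<sim_design> %d cells x %d genes, %d groups (%s), de_prob %s, dropout %s\n",
    x$n_cells, x$n_genes, x$n_groups,
    paste(x$group_prob, collapse = "/"),
    paste(x$de_prob, collapse = "/"),
    if (is.na(x$dropout_mid)) "off" else paste0("mid=", x$dropout_mid)))
  invisible(x)
}

#' The three stock simulation designs
#'
#' Three 600-cell x 5000-gene designs of increasing realism used throughout
#' the package's tests and examples:
#' \describe{
#'   \item{simdata1}{4 equally abundant groups (0.25 each), DE probabilities
#'     0.05/0.1/0.2/0.4, no dropout.}
#'   \item{simdata2}{4 groups with unequal abundances 0.35/0.4/0.15/0.1,
#'     same DE probabilities, dropout midpoint 2.}
#'   \item{simdata3}{5 groups with abundances 0.15/0.20/0.40/0.15/0.10, DE
#'     probabilities 0.15/0.1/0.1/0.1/0.2, dropout midpoint 1.}
#' }
#'
#' @return Named list of three [sim_design()] objects.
#' @examples
#' sim_presets()$simdata3$group_prob
#' @export
sim_presets <- function() {
  list(
    simdata1 = sim_design(group_prob = rep(0.25, 4),
                          de_prob = c(0.05, 0.1, 0.2, 0.4)),
    simdata2 = sim_design(group_prob = c(0.35, 0.4, 0.15, 0.1),
                          de_prob = c(0.05, 0.1, 0.2, 0.4),
                          dropout_mid = 2),
    simdata3 = sim_design(group_prob = c(0.15, 0.20, 0.40, 0.15, 0.10),
                          de_prob = c(0.15, 0.1, 0.1, 0.1, 0.2),
                          dropout_mid = 1))
}

#' Simulate a grouped scRNA-seq count matrix
#'
#' Draws counts from the generative model described in [sim_design()]:
#' \enumerate{
#'   \item baseline gene means `mu_g ~ Gamma(mean_shape, mean_rate)`;
#'   \item per group, each gene is DE with probability `de_prob[k]`; DE
#'     genes receive a log-normal factor, inverted (`1/f`) with probability
#'     1/2, giving group means `mu_gk`;
#'   \item cells are assigned to groups multinomially with `group_prob`;
#'   \item per-cell library sizes `L_c ~ LogNormal(lib_loc, lib_scale)`;
#'     expected expression `lambda_gc = mu_g,group(c) / sum_g mu_g,group(c)
#'     * L_c`, so each cell's expected total count is `L_c`;
#'   \item over-dispersion: `lambda' = lambda * Gamma(1/bcv^2, scale =
#'     bcv^2)` (mean 1);
#'   \item `counts ~ Poisson(lambda')`;
#'   \item optional dropout: each entry is zeroed with probability
#'     `1 / (1 + exp(dropout_shape * (log(lambda + 1) - dropout_mid)))`,
#'     computed from the pre-dispersion expectation.
#' }
#' Identical design + seed gives bit-identical output.
#'
#' @param design a [sim_design()].
#' @param seed RNG seed; defaults to the design's own.
#' @return List with `counts` (an [count_matrix()]), `labels` (integer group
#'   per cell, named by cell id) and `design`.
#' @examples
#' sim <- simulate_counts(sim_design(n_cells = 40, n_genes = 300, seed = 7))
#' table(sim$labels)
#' @export
simulate_counts <- function(design, seed = design$seed) {
  validate_design(design)
  p <- design$n_genes; n <- design$n_cells; K <- design$n_groups
  withr::with_seed(seed, {
    mu <- rgamma(p, shape = design$mean_shape, rate = design$mean_rate)
    fac <- matrix(1, p, K)
    for (k in seq_len(K)) {
      de <- runif(p) < design$de_prob[k]
      nde <- sum(de)
      if (nde > 0) {
        f <- rlnorm(nde, design$de_fac_loc, design$de_fac_scale)
        flip <- runif(nde) < 0.5
        f[flip] <- 1 / f[flip]
        fac[de, k] <- f
      }
    }
    mu_gk <- mu * fac                       # p x K group means
    groups <- sample.int(K, n, replace = TRUE, prob = design$group_prob)
    lib <- rlnorm(n, design$lib_loc, design$lib_scale)
    group_tot <- colSums(mu_gk)
    lam <- mu_gk[, groups, drop = FALSE]
    lam <- sweep(lam, 2, group_tot[groups], "/")
    lam <- sweep(lam, 2, lib, "*")          # expected expression, p x n
    disp <- matrix(rgamma(p * n, shape = 1 / design$bcv^2,
                          scale = design$bcv^2), p, n)
    counts <- matrix(rpois(p * n, lam * disp), p, n)
    if (!is.na(design$dropout_mid)) {
      pi_drop <- 1 / (1 + exp(design$dropout_shape *
                                (log(lam + 1) - design$dropout_mid)))
      counts[matrix(runif(p * n), p, n) < pi_drop] <- 0L
    }
    cm <- count_matrix(counts,
                       gene_ids = paste0("g", seq_len(p)),
                       cell_ids = paste0("c", seq_len(n)))
    list(counts = cm,
         labels = stats::setNames(groups, colnames(cm)),
         design = design)
  })
}
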