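# Independent brute-force oracles used to validate the package's
# implementations. Deliberately written with different algorithms / code
# paths than the functions they check.

# quantile normalization by direct definition: reference = mean of sorted
# columns; ties within a column get the mean reference value of their span
quantile_norm_oracle <- function(X) {
  ref <- rowMeans(apply(X, 2, sort))
  apply(X, 2, function(col) {
    out <- numeric(length(col))
    srt <- sort(col)
    for (v in unique(col))
      out[col == v] <- mean(ref[which(srt == v)])
    out
  })
}

# NMI by the joint-entropy route: I = H(t) + H(d) - H(t,d)
nmi_oracle <- function(truth, detected) {
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  ht <- ent(truth); hd <- ent(detected)
  hj <- ent(paste(truth, detected, sep = "\r"))
  if (ht == 0 && hd == 0) return(1)
  if (ht == 0 || hd == 0) return(0)
  (ht + hd - hj) / sqrt(ht * hd)
}

# ARI by explicit pair counting over all n(n-1)/2 pairs
ari_pairs_oracle <- function(truth, detected) {
  n <- length(truth)
  st <- outer(truth, truth, "==")[upper.tri(diag(n))]
  sd_ <- outer(detected, detected, "==")[upper.tri(diag(n))]
  a <- sum(st & sd_); b <- sum(st & !sd_)
  c_ <- sum(!st & sd_); d <- sum(!st & !sd_)
  expected <- (a + b) * (a + c_) / (a + b + c_ + d)
  max_index <- ((a + b) + (a + c_)) / 2
  if (max_index == expected) return(1)
  (a - expected) / (max_index - expected)
}

# modularity by the raw double sum (no grouping tricks)
modularity_oracle <- function(W, labels) {
  n <- nrow(W)
  m2 <- sum(W)
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (labels[i] == labels[j])
      q <- q + W[i, j] - k[i] * k[j] / m2
  q / m2
}

# all set partitions of n elements as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_max) {
    i <- length(labels) + 1
    if (i > n) { out[[length(out) + 1]] <<- labels; return(invisible()) }
    for (c in seq_len(next_max + 1))
      rec(c(labels, c), max(next_max, c))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive maximum modularity over all partitions (n small)
max_modularity_exhaustive <- function(W, mode = "standard") {
  best <- -Inf
  for (p in all_partitions(nrow(W))) {
    q <- modularity_q(W, p, mode = mode)
    if (q > best) best <- q
  }
  best
}

# a block-structured adjacency with given block sizes, for community and
# embedding tests
block_adjacency <- function(sizes, intra = 0.8, inter = 0.02, noise = 0.05,
                            seed = 1) {
  withr::with_seed(seed, {
    n <- sum(sizes)
    lab <- rep(seq_along(sizes), sizes)
    W <- matrix(inter, n, n) + matrix(runif(n * n, 0, noise), n, n)
    W[outer(lab, lab, "==")] <- intra
    W <- (W + t(W)) / 2
    diag(W) <- 0
    list(W = W, labels = lab)
  })
}

# small simulated dataset + full pipeline, for pipeline-level tests
quick_sim <- function(n_cells = 80, n_genes = 400, groups = 3, de_prob = 1,
                      seed = 1, ...) {
  simulate_counts(sim_design(n_cells = n_cells, n_genes = n_genes,
                             group_prob = rep(1 / groups, groups),
                             de_prob = de_prob, seed = seed, ...))
}
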