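test_that("modularity matches hand values and the brute-force formula", {
  # two disconnected 2-cliques split by component: Q = 1/2
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  expect_equal(modularity_q(W, c(1, 1, 2, 2)), 0.5)
  expect_equal(modularity_oracle(W, c(1, 1, 2, 2)), 0.5)
  # ... and no other partition of the 4 nodes does better
  expect_equal(max_modularity_exhaustive(W), 0.5)
  # everything in one cluster is exactly 0, for any weighted graph
  for (seed in 1:3) {
    Wr <- withr::with_seed(seed, {
      A <- matrix(runif(49), 7); A <- (A + t(A)) / 2; diag(A) <- 0; A
    })
    expect_equal(modularity_q(Wr, rep(1, 7)), 0)
    # agreement with the double-sum oracle on arbitrary partitions
    lab <- withr::with_seed(seed, sample(1:3, 7, replace = TRUE))
    expect_equal(modularity_q(Wr, lab), modularity_oracle(Wr, lab),
                 tolerance = 1e-12)
    # invariant under relabeling
    expect_equal(modularity_q(Wr, lab), modularity_q(Wr, 4 - lab))
  }
  # guard rails
  expect_error(modularity_q(matrix(0, 3, 3), rep(1, 3)), "empty graph")
  Wn <- W; Wn[1, 2] <- Wn[2, 1] <- -1
  expect_error(modularity_q(Wn, c(1, 1, 2, 2)), "signed")
})

test_that("signed modularity decomposes into weighted layers", {
  W <- rbind(c(0, 0.9, -0.5), c(0.9, 0, 0.2), c(-0.5, 0.2, 0))
  lab <- c(1, 1, 2)
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  mp <- sum(Wp) / 2; mn <- sum(Wn) / 2
  manual <- (mp * modularity_oracle(Wp, lab) -
             mn * modularity_oracle(Wn, lab)) / (mp + mn)
  expect_equal(modularity_q(W, lab, mode = "signed"), manual,
               tolerance = 1e-12)
  # on a nonnegative graph the signed score reduces to the standard one
  expect_equal(modularity_q(Wp, lab, mode = "signed"),
               modularity_q(Wp, lab, mode = "standard"))
})

test_that("louvain recovers unambiguous block structure for every seed", {
  blocks <- block_adjacency(c(8, 8, 8), intra = 0.9, inter = 0, noise = 0.01)
  for (seed in c(0, 1, 42)) {
    part <- louvain_cluster(blocks$W, restarts = 3, seed = seed)
    expect_equal(part$n_clusters, 3)
    expect_equal(ari(blocks$labels, part$labels), 1)
  }
})

test_that("louvain results are deterministic and improve with restarts", {
  blocks <- block_adjacency(c(6, 6, 6), intra = 0.5, inter = 0.1,
                            noise = 0.3, seed = 9)
  p1 <- louvain_cluster(blocks$W, restarts = 5, seed = 7)
  p2 <- louvain_cluster(blocks$W, restarts = 5, seed = 7)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$Q, p2$Q)
  # max over a superset of restarts can only help
  q1 <- louvain_cluster(blocks$W, restarts = 1, seed = 3)$Q
  q10 <- louvain_cluster(blocks$W, restarts = 10, seed = 3)$Q
  expect_gte(q10, q1)
  # stored Q is the recomputed modularity of the labels
  expect_equal(p1$Q, modularity_q(blocks$W, p1$labels, mode = p1$mode),
               tolerance = 1e-10)
  # beats the trivial partitions
  expect_gte(p1$Q, 0)
})

test_that("degenerate graphs are handled explicitly", {
  expect_warning(p <- louvain_cluster(matrix(0, 5, 5)), "all-zero")
  expect_equal(p$n_clusters, 1)
  expect_error(louvain_cluster(matrix(0, 1, 1)), "at least 2")
  Wn <- rbind(c(0, -1), c(-1, 0))
  expect_error(louvain_cluster(Wn, mode = "standard"), "signed")
})

test_that("signed optimizer finds the exhaustive optimum on small graphs", {
  hits <- 0
  for (seed in 1:12) {
    W <- withr::with_seed(seed, {
      A <- matrix(runif(36, -0.4, 1), 6)
      mask <- withr::with_seed(seed + 100, matrix(runif(36), 6)) < 0.4
      A[mask] <- 0
      A <- (A + t(A)) / 2; diag(A) <- 0; A
    })
    if (all(W == 0) || all(W >= 0)) next
    best <- max_modularity_exhaustive(W, mode = "signed")
    got <- louvain_cluster(W, restarts = 10, seed = 1, mode = "signed")$Q
    expect_lte(got, best + 1e-9)
    if (abs(got - best) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 10)  # heuristic: allow isolated misses, not a trend
})
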