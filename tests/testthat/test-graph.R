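test_that("lambda defaults follow the information-criterion convention", {
  expect_equal(default_lambda(criterion = "aic"), 2)
  expect_equal(default_lambda(5000), log(5000))
  expect_equal(default_lambda(5000, "bic"), 8.5171932, tolerance = 1e-6)
  expect_equal(default_lambda(criterion = "custom", value = 0.1), 0.1)
  expect_error(default_lambda(criterion = "custom"), "value")
  expect_error(default_lambda(criterion = "custom", value = -1),
               "nonnegative")
  expect_error(default_lambda(p = 1, criterion = "bic"), "p >= 2")
})

test_that("compute_S inverts the regularized Gram matrix", {
  # orthonormal columns: S = (I + lambda I)^-1
  X <- diag(4)[, 1:3]
  expect_equal(compute_S(X, 1), diag(3) / 2)
  # two unit columns with inner product 0.8, lambda = 1: hand inverse
  X2 <- cbind(c(1, 0, 0), c(0.8, 0.6, 0))
  S2 <- compute_S(X2, 1)
  expect_equal(S2, rbind(c(2, -0.8), c(-0.8, 2)) / 3.36, tolerance = 1e-12)
  expect_equal(S2, rbind(c(0.5952381, -0.2380952),
                         c(-0.2380952, 0.5952381)), tolerance = 1e-7)
  # S * (X'X + lambda I) = I for random problems
  for (seed in 1:5) {
    X3 <- withr::with_seed(seed, matrix(rnorm(15 * 8), 15, 8))
    lam <- c(0.1, 2, 100)[seed %% 3 + 1]
    A <- crossprod(X3) + lam * diag(8)
    expect_lt(max(abs(compute_S(X3, lam) %*% A - diag(8))), 1e-6)
  }
  # lambda -> Inf limit: lambda * S -> I
  expect_equal(1e9 * compute_S(X2, 1e9), diag(2), tolerance = 1e-6)
  # singular Gram at lambda = 0 (more cells than genes) is refused
  Xs <- withr::with_seed(1, matrix(rnorm(3 * 6), 3, 6))
  expect_error(compute_S(Xs, 0), "positive lambda")
})

test_that("compute_W applies the three normalizations and the constraints", {
  X2 <- cbind(c(1, 0, 0), c(0.8, 0.6, 0))
  S2 <- compute_S(X2, 1)
  g_sym <- compute_W(S2, 1, normalization = "symmetric")
  expect_equal(g_sym$W[1, 2], 0.4, tolerance = 1e-12)   # -s12/sqrt(s11 s22)
  expect_equal(diag(g_sym$W), c(0, 0), ignore_attr = TRUE)
  g_none <- compute_W(S2, 1, normalization = "none")
  expect_equal(g_none$W[1, 2], -1 * S2[1, 2], tolerance = 1e-12)
  g_col <- compute_W(S2, 1, normalization = "column", symmetrize = FALSE)
  expect_equal(g_col$W[1, 2], -S2[1, 2] / S2[2, 2], tolerance = 1e-12)
  # no edges between orthogonal cells
  g0 <- compute_W(compute_S(diag(4)[, 1:3], 1), 1)
  expect_true(all(g0$W == 0))
  # symmetric normalization keeps weights in (-1, 1) for random PD S
  for (seed in 1:10) {
    A <- withr::with_seed(seed, {
      B <- matrix(rnorm(36), 6)
      crossprod(B) + diag(6) * 0.5
    })
    S <- solve(A)
    w <- compute_W(S, 1, normalization = "symmetric")$W
    expect_true(all(abs(w[upper.tri(w)]) < 1))
  }
  # clipping removes negatives
  gc <- compute_W(S2, 1, normalization = "none", clip_negative = TRUE)
  expect_true(all(gc$W >= 0))
  expect_error(compute_W(matrix(c(1, 0, 0, -1), 2), 1), "1e-12")
})

test_that("the closed form equals the per-column ridge solutions", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      p <- sample(10:20, 1); n <- sample(4:9, 1)
      X <- matrix(rnorm(p * n), p, n)
      lam <- sample(c(0.1, 1, 10), 1)
      S <- compute_S(X, lam)
      # identity of the closed form: (X'X + lam I)^-1 X'X = I - lam S
      lhs <- solve(crossprod(X) + lam * diag(n), crossprod(X))
      expect_lt(max(abs(lhs - (diag(n) - lam * S))), 1e-8)
      # each column of the unconstrained solution is a ridge fit of x_j on X
      j <- sample(n, 1)
      wj <- solve(crossprod(X) + lam * diag(n), crossprod(X, X[, j]))
      expect_lt(max(abs(lhs[, j] - wj)), 1e-10)
    })
  }
})

test_that("ridge oracle shrinks, improves on zero, and obeys the L2 bound", {
  X <- withr::with_seed(2, {
    X <- matrix(rnorm(30 * 10), 30, 10)
    sweep(X, 2, sqrt(colSums(X^2)), "/")   # unit-norm columns
  })
  # heavy shrinkage kills all coefficients
  expect_lt(max(abs(ridge_oracle(X, 1e8, 3))), 1e-6)
  for (j in 1:10) {
    w <- ridge_oracle(X, 2, j)
    expect_equal(w[j], 0)
    obj <- sum((X[, j] - X %*% w)^2) + 2 * sum(w^2)
    expect_lte(obj, sum(X[, j]^2) + 1e-12)   # no worse than w = 0
    # grouping-effect bound for every pair k < l
    for (k in setdiff(1:9, j)) for (l in setdiff((k + 1):10, j)) {
      bound <- sqrt(pmax(0, 2 * (1 - sum(X[, k] * X[, l])))) / 2
      expect_lte(abs(w[k] - w[l]), bound + 1e-12)
    }
  }
})

test_that("duplicated cells receive exactly equal coefficients", {
  X <- withr::with_seed(5, matrix(rnorm(40 * 6), 40, 6))
  X <- cbind(X, X[, 2])   # cell 7 duplicates cell 2
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  g <- compute_W(compute_S(X, 2), 2, normalization = "symmetric",
                 symmetrize = FALSE, clip_negative = FALSE)
  for (j in setdiff(1:7, c(2, 7)))
    expect_equal(g$W[2, j], g$W[7, j], tolerance = 1e-10)
})

test_that("two-cell affinity grows with correlation and survives lambda", {
  # monotone in the inner product c at fixed lambda
  w12 <- vapply(seq(0.05, 0.95, by = 0.1), function(cc) {
    X <- cbind(c(1, 0), c(cc, sqrt(1 - cc^2)))
    compute_W(compute_S(X, 1), 1)$W[1, 2]
  }, numeric(1))
  expect_true(all(diff(w12) > 0))
  # rank order of the off-diagonal W is stable over the whole lambda range
  # an information criterion would pick (lambda << tr(X'X)/n = p); this is
  # the mechanism behind the clustering's lambda-robustness
  sim <- quick_sim(n_cells = 50, n_genes = 2000, de_prob = 0.3, seed = 6)
  X <- preprocess_counts(sim$counts)
  up <- upper.tri(matrix(0, 50, 50))
  ws <- lapply(c(0.01, 2, log(2000), 2 * log(2000)), function(lam)
    compute_W(compute_S(X, lam), lam, normalization = "none")$W[up])
  for (i in seq_along(ws)[-1])
    expect_gt(cor(ws[[1]], ws[[i]], method = "spearman"), 0.99)
})
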