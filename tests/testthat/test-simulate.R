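test_that("the stock designs encode the three study conditions", {
  p <- sim_presets()
  expect_named(p, c("simdata1", "simdata2", "simdata3"))
  expect_equal(p$simdata1$n_groups, 4)
  expect_equal(p$simdata1$group_prob, rep(0.25, 4))
  expect_equal(p$simdata1$de_prob, c(0.05, 0.1, 0.2, 0.4))
  expect_true(is.na(p$simdata1$dropout_mid))
  expect_equal(p$simdata2$group_prob, c(0.35, 0.4, 0.15, 0.1))
  expect_equal(p$simdata2$dropout_mid, 2)
  expect_equal(p$simdata3$group_prob, c(0.15, 0.20, 0.40, 0.15, 0.10))
  expect_equal(p$simdata3$de_prob, c(0.15, 0.1, 0.1, 0.1, 0.2))
  expect_equal(p$simdata3$dropout_mid, 1)
  for (d in p) {
    expect_equal(d$n_cells, 600L)
    expect_equal(d$n_genes, 5000L)
  }
})

test_that("designs are validated before any sampling", {
  expect_error(sim_design(group_prob = c(0.5, 0.6)), "sum to 1")
  expect_error(sim_design(group_prob = c(1.2, -0.2)), "sum to 1|positive")
  expect_error(sim_design(de_prob = c(0.1, 2)), "de_prob")
  expect_error(sim_design(bcv = 0), "bcv")
  expect_error(sim_design(n_cells = 1), "at least 2")
  d <- sim_design(de_prob = 0.2, group_prob = rep(1 / 3, 3))
  expect_equal(d$de_prob, rep(0.2, 3))  # recycled per group
})

test_that("simulation is bit-reproducible from design + seed", {
  d <- sim_design(n_cells = 30, n_genes = 150, seed = 5)
  s1 <- simulate_counts(d)
  s2 <- simulate_counts(d)
  expect_identical(unclass(s1$counts), unclass(s2$counts))
  expect_identical(s1$labels, s2$labels)
  s3 <- simulate_counts(d, seed = 6)
  expect_false(identical(unclass(s1$counts), unclass(s3$counts)))
})

test_that("marginal behavior tracks the generative knobs", {
  # richer libraries -> larger counts
  lo <- simulate_counts(sim_design(n_cells = 60, n_genes = 400,
                                   lib_loc = 8, seed = 2))
  hi <- simulate_counts(sim_design(n_cells = 60, n_genes = 400,
                                   lib_loc = 10, seed = 2))
  expect_gt(mean(hi$counts), mean(lo$counts))
  # dropout midpoint pushes the zero fraction up monotonically
  zfrac <- vapply(c(NA, 0.5, 2, 4), function(mid)
    mean(simulate_counts(sim_design(n_cells = 60, n_genes = 400,
                                    dropout_mid = mid, seed = 3))$counts == 0),
    numeric(1))
  expect_true(all(diff(zfrac) > 0))
  # group sizes are multinomial around the requested abundances
  sim <- simulate_counts(sim_presets()$simdata1, seed = 1)
  expect_equal(dim(sim$counts), c(5000L, 600L))
  sizes <- as.integer(table(sim$labels))
  expect_length(sizes, 4)
  expect_true(all(sizes > 100 & sizes < 200))  # ~150 each
})

test_that("separability of the design drives downstream recovery", {
  # no DE at all: clustering cannot beat chance
  null_nmi <- vapply(1:3, function(s) {
    sim <- quick_sim(n_cells = 90, n_genes = 400, de_prob = 0, seed = s)
    fit <- rggc_cluster(sim$counts, restarts = 3, seed = 0)
    nmi(sim$labels, fit$partition$labels)
  }, numeric(1))
  expect_lt(mean(null_nmi), 0.2)
  # fully separated design: perfect recovery across seeds
  for (s in 1:5) {
    sim <- quick_sim(n_cells = 90, n_genes = 400, de_prob = 1,
                     de_fac_scale = 1, seed = s)
    fit <- rggc_cluster(sim$counts, restarts = 3, seed = 0)
    expect_equal(nmi(sim$labels, fit$partition$labels), 1)
  }
  # stronger DE -> monotonically better mean NMI
  mean_nmi <- vapply(c(0.02, 0.3, 1), function(dp) {
    mean(vapply(1:5, function(s) {
      sim <- quick_sim(n_cells = 90, n_genes = 400, de_prob = dp, seed = s)
      fit <- rggc_cluster(sim$counts, restarts = 3, seed = 0)
      nmi(sim$labels, fit$partition$labels)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_nmi) >= 0))
})
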