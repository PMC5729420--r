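# Direct (squared partial correlation), indirect (penalized logistic) and
# rank-combined evidence.

make_prior <- function(M) {
  structure(
    list(M = M, tf_ids = colnames(M), gene_ids = rownames(M)),
    class = "motif_prior"
  )
}

test_that("direct evidence recovers exact correlations in closed-form cases", {
  # one TF, two genes, no conditioning (empty motif rows)
  M <- matrix(0, 2, 1, dimnames = list(c("GA", "GB"), "TF1"))
  E <- rbind(
    TF1 = c(1, -1, 1, -1),
    GA = c(1, -1, 1, -1), # identical to the TF
    GB = c(1, 1, -1, -1) # orthogonal, zero mean
  )
  d <- direct_evidence(E, make_prior(M))
  expect_equal(d["GA", "TF1"], 1.0)
  expect_equal(d["GB", "TF1"], 0.0)
})

test_that("direct evidence matches the residualize-and-correlate oracle", {
  # n = 6 samples, one conditioning TF per gene
  set.seed(31)
  genes <- sprintf("G%d", 1:5)
  tfs <- c("TF1", "TF2")
  E <- matrix(rnorm(7 * 6), 7, 6, dimnames = list(c(tfs, genes), NULL))
  M <- matrix(0, 5, 2, dimnames = list(genes, tfs))
  M[, "TF2"] <- 1 # TF2 conditions every gene's pairing with TF1
  d <- direct_evidence(E, make_prior(M))
  for (g in genes) {
    expect_equal(
      d[g, "TF1"],
      oracle_sq_pcor(E["TF1", ], E[g, ], E["TF2", ]),
      tolerance = 1e-10
    )
    # TF2 is in the motif set, so its own conditioning set is empty
    expect_equal(
      d[g, "TF2"],
      oracle_sq_pcor(E["TF2", ], E[g, ]),
      tolerance = 1e-10
    )
  }
})

test_that("direct evidence is invariant to sample order and bounded", {
  sim <- simulate_regulatory_data(
    p = 30, m = 4, targets_per_gene = 2,
    n_per_group = c(10, 10), seed = 3
  )
  h <- harmonize(sim$expr, sim$prior)
  E <- h$expr$values[, group_samples(h$expr, "initial")]
  d1 <- direct_evidence(E, h$prior)
  set.seed(1)
  d2 <- direct_evidence(E[, sample(ncol(E))], h$prior)
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_true(all(d1 >= 0 & d1 <= 1))
})

test_that("all-zero prior reduces direct evidence to squared Pearson", {
  set.seed(8)
  genes <- sprintf("G%d", 1:6)
  tfs <- c("TF1", "TF2")
  E <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(c(tfs, genes), NULL))
  M <- matrix(0, 6, 2, dimnames = list(genes, tfs))
  d <- direct_evidence(E, make_prior(M))
  expect_equal(
    d,
    cor(t(E[genes, ]), t(E[tfs, ]))^2,
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("zero-variance residuals give evidence 0, not NaN", {
  # gene identical to its sole conditioning TF: residual vanishes
  genes <- c("G1", "G2")
  tfs <- c("TF1", "TF2")
  set.seed(4)
  E <- matrix(rnorm(4 * 8), 4, 8, dimnames = list(c(tfs, genes), NULL))
  E["G1", ] <- E["TF2", ]
  M <- matrix(0, 2, 2, dimnames = list(genes, tfs))
  M["G1", "TF2"] <- 1 # pairing G1 with TF1 conditions on TF2 == G1
  d <- direct_evidence(E, make_prior(M))
  expect_identical(d["G1", "TF1"], 0)
  expect_true(all(is.finite(d)))
})

test_that("conditioning sets wider than n - 2 fall back with a warning", {
  genes <- sprintf("G%d", 1:3)
  tfs <- sprintf("TF%d", 1:4)
  set.seed(5)
  E <- matrix(rnorm(7 * 4), 7, 4, dimnames = list(c(tfs, genes), NULL))
  M <- matrix(1, 3, 4, dimnames = list(genes, tfs)) # |C| = 3 > n - 2 = 2
  expect_warning(d <- direct_evidence(E, make_prior(M)), "minimum-norm")
  expect_true(all(is.finite(d)))
})

test_that("indirect evidence handles degenerate and constant designs", {
  genes <- sprintf("G%d", 1:6)
  tfs <- c("TF1", "TF2")
  set.seed(6)
  E <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(c(tfs, genes), NULL))
  M <- matrix(0, 6, 2, dimnames = list(genes, tfs))
  M[, "TF1"] <- 1 # all-ones response
  M[1:2, "TF2"] <- 1
  expect_warning(th <- indirect_evidence(E, make_prior(M)), "constant motif")
  expect_true(all(th$theta[, "TF1"] >= 0.99))

  # constant predictors: intercept-only fit returns the prevalence
  E2 <- E
  E2[genes, ] <- 1.5
  th2 <- suppressWarnings(indirect_evidence(E2, make_prior(M)))
  expect_equal(unname(th2$theta[, "TF2"]), rep(1 / 3, 6), tolerance = 1e-8)
})

test_that("indirect evidence matches the penalized-logistic oracle", {
  # p = 8 genes, N = 3 samples, mixed response
  genes <- sprintf("G%d", 1:8)
  tfs <- c("TF1", "TF2")
  set.seed(7)
  E <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(c(tfs, genes), NULL))
  M <- matrix(0, 8, 2, dimnames = list(genes, tfs))
  M[c(1, 4, 6), "TF1"] <- 1
  M[c(2, 3, 5, 7), "TF2"] <- 1
  th <- indirect_evidence(E, make_prior(M))
  Z <- E[genes, ]
  for (tf in tfs) {
    expect_equal(
      unname(th$theta[, tf]),
      unname(oracle_penalized_logistic(Z, M[, tf])),
      tolerance = 1e-6
    )
  }
})

test_that("fitted indirect evidence reproduces the response prevalence", {
  sim <- simulate_regulatory_data(
    p = 60, m = 5, targets_per_gene = 2,
    n_per_group = c(12, 12), seed = 12
  )
  h <- harmonize(sim$expr, sim$prior)
  E <- h$expr$values[, group_samples(h$expr, "initial")]
  th <- indirect_evidence(E, h$prior)
  # unpenalized intercept makes column means match base rates
  expect_equal(colMeans(th$theta), colMeans(h$prior$M), tolerance = 1e-6)
  expect_true(all(th$theta >= 0 & th$theta <= 1))
})

test_that("combine_evidence does rank arithmetic per column", {
  d <- matrix(c(0.9, 0.1, 0.5), 3, 1)
  th <- matrix(c(0.2, 0.8, 0.5), 3, 1)
  # ranks d: (3,1,2), theta: (1,3,2); combined (2,2,2); normalized by p = 3
  expect_equal(combine_evidence(d, th, 0.5), matrix(2 / 3, 3, 1))
  # endpoints pick a single evidence source
  expect_equal(combine_evidence(d, th, 0), matrix(c(3, 1, 2) / 3, 3, 1))
  expect_equal(combine_evidence(d, th, 1), matrix(c(1, 3, 2) / 3, 3, 1))
  expect_error(combine_evidence(d, th, 1.2), "alpha")
  expect_error(combine_evidence(d, th, -0.1), "alpha")
})

test_that("combine_evidence sees only ranks (monotone-transform invariant)", {
  set.seed(13)
  d <- matrix(runif(40), 10, 4)
  th <- matrix(runif(40), 10, 4)
  w1 <- combine_evidence(d, th, 0.3)
  w2 <- combine_evidence(d^3, exp(2 * th), 0.3)
  expect_equal(w1, w2)
  expect_true(all(w1 > 0 & w1 <= 1))
})

test_that("infer_network is deterministic with default alpha 0.5", {
  sim <- simulate_regulatory_data(
    p = 40, m = 4, targets_per_gene = 2,
    n_per_group = c(10, 10), seed = 21
  )
  h <- harmonize(sim$expr, sim$prior)
  n1 <- infer_network(h$expr, h$prior, "initial")
  n2 <- infer_network(h$expr, h$prior, "initial")
  expect_identical(n1$weights, n2$weights)
  expect_equal(n1$alpha, 0.5)
  expect_equal(
    n1$weights,
    combine_evidence(n1$direct, n1$indirect, 0.5)
  )
})

test_that("inferred weights rank true motif targets above non-targets", {
  sim <- simulate_regulatory_data(
    p = 100, m = 6, targets_per_gene = 2,
    n_per_group = c(25, 25), effect_size = 1, noise_sd = 0.5, seed = 30
  )
  h <- harmonize(sim$expr, sim$prior)
  net <- infer_network(h$expr, h$prior, "initial")
  on_motif <- net$weights[h$prior$M == 1]
  off_motif <- net$weights[h$prior$M == 0]
  expect_gt(mean(on_motif), mean(off_motif))
})
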