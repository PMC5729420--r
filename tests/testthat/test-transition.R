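# Transition-matrix estimation: exact algebra, oracle agreement, penalties.

test_that("identical states give the identity transition", {
  nets <- random_networks(50, 5, seed = 1)
  tr <- estimate_transition(nets$A, nets$A)
  expect_lt(max(abs(tr$T_diff)), 1e-8)
  expect_lt(max(abs(tr$T_full - diag(5))), 1e-8)
  expect_identical(tr$method, "ols")
  expect_identical(colnames(tr$T_full), colnames(nets$A))
})

test_that("OLS residual columns are orthogonal to the column space of A", {
  nets <- random_networks(60, 6, seed = 2)
  tr <- estimate_transition(nets$A, nets$B)
  expect_lt(
    max(abs(crossprod(nets$A, tr$residuals))),
    1e-6 * norm(nets$A, "F")
  )
  # and T_full - T_diff is the identity
  expect_lt(max(abs(tr$T_full - tr$T_diff - diag(6))), 1e-8)
})

test_that("replacing one column of A is read off exactly in T_full", {
  nets <- random_networks(50, 5, seed = 3)
  B <- nets$A
  B[, 2] <- nets$A[, 4]
  tr <- estimate_transition(nets$A, B)
  expected <- diag(5)
  expected[, 2] <- 0
  expected[4, 2] <- 1
  expect_lt(max(abs(unname(tr$T_full) - expected)), 1e-8)
})

test_that("noiseless linear maps are recovered and match the pinv oracle", {
  set.seed(4)
  A <- matrix(rnorm(60 * 6), 60, 6)
  T_true <- matrix(rnorm(36), 6, 6)
  B <- A %*% T_true
  tr <- estimate_transition(A, B)
  expect_lt(max(abs(tr$T_full - T_true)), 1e-8)
  expect_lt(max(abs(tr$T_full - (oracle_pinv(A) %*% B))), 1e-8)
})

test_that("difference and direct regressions agree on full-rank designs", {
  for (s in 1:10) {
    nets <- random_networks(40, 5, seed = 100 + s)
    expect_true(equivalence_check(nets$A, nets$B))
  }
  # identity design: T_full is literally B
  B <- matrix(rnorm(16), 4, 4)
  tr <- estimate_transition(diag(4), B)
  expect_equal(unname(tr$T_full), B, tolerance = 1e-10)
  expect_true(equivalence_check(diag(4), B))
  # rank-deficient A: check declines with a warning
  A_def <- cbind(1:6, 2 * (1:6), rnorm(6))
  expect_warning(res <- equivalence_check(A_def, A_def), "rank-deficient")
  expect_true(is.na(res))
})

test_that("the OLS solution minimizes the per-column residual norm", {
  nets <- random_networks(40, 5, seed = 7)
  tr <- estimate_transition(nets$A, nets$B)
  Y <- nets$B - nets$A
  base <- colSums((Y - nets$A %*% tr$T_diff)^2)
  set.seed(77)
  for (r in 1:100) {
    Tp <- tr$T_diff + matrix(rnorm(25, sd = 1e-3), 5, 5)
    expect_true(all(colSums((Y - nets$A %*% Tp)^2) >= base))
  }
})

test_that("ridge converges to OLS as the penalty vanishes", {
  nets <- random_networks(60, 6, seed = 8)
  ols <- estimate_transition(nets$A, nets$B)
  ridge <- estimate_transition(nets$A, nets$B,
    method = "ridge",
    penalty = 1e-10
  )
  expect_lt(max(abs(ridge$T_diff - ols$T_diff)), 1e-6)
  # and a visible penalty shrinks coefficients
  heavy <- estimate_transition(nets$A, nets$B, method = "ridge", penalty = 50)
  expect_lt(sum(heavy$T_diff^2), sum(ols$T_diff^2))
})

test_that("ridge solves its normal equations exactly", {
  nets <- random_networks(30, 4, seed = 9)
  lam <- 2.5
  ridge <- estimate_transition(nets$A, nets$B, method = "ridge", penalty = lam)
  Y <- nets$B - nets$A
  expected <- solve(
    crossprod(nets$A) + lam * diag(4),
    crossprod(nets$A, Y)
  )
  expect_lt(max(abs(ridge$T_diff - expected)), 1e-10)
})

test_that("lasso sparsifies and matches glmnet on its shared objective", {
  nets <- random_networks(80, 5, seed = 10)
  Y <- nets$B - nets$A
  # large enough penalty zeroes the whole transition difference
  lam_max <- 2 * max(abs(crossprod(nets$A, Y)))
  all_zero <- estimate_transition(nets$A, nets$B,
    method = "lasso",
    penalty = lam_max * 1.01
  )
  expect_true(all(all_zero$T_diff == 0))
  expect_lt(max(abs(all_zero$T_full - diag(5))), 1e-12)

  # moderate penalty: cross-check column 1 against glmnet, which minimizes
  # (1/2n)||y - Ab||^2 + lambda_g ||b||_1  ==  ours with lambda = 2n lambda_g
  lam <- 0.5
  ours <- estimate_transition(nets$A, nets$B, method = "lasso", penalty = lam)
  g <- glmnet::glmnet(nets$A, Y[, 1],
    lambda = lam / (2 * nrow(nets$A)),
    intercept = FALSE, standardize = FALSE, thresh = 1e-14
  )
  expect_lt(max(abs(ours$T_diff[, 1] - as.numeric(g$beta))), 1e-6)
})

test_that("TF permutation permutes the transition consistently", {
  nets <- random_networks(40, 5, seed = 11)
  tr <- estimate_transition(nets$A, nets$B)
  perm <- c(3, 1, 5, 2, 4)
  tr_p <- estimate_transition(nets$A[, perm], nets$B[, perm])
  expect_equal(tr_p$T_full, tr$T_full[perm, perm], tolerance = 1e-10)
})

test_that("degenerate inputs are caught or flagged", {
  nets <- random_networks(30, 4, seed = 12)
  bad <- nets$B
  bad[2, 2] <- NaN
  expect_error(estimate_transition(nets$A, bad), "finite")
  expect_error(estimate_transition(nets$A, nets$B[, 1:3]), "same shape")
  expect_error(
    estimate_transition(nets$A, nets$B, method = "ols", penalty = 1),
    "penalty"
  )
  # duplicated TF column: singular A'A, minimum-norm answer with warning
  A_dup <- nets$A
  A_dup[, 2] <- A_dup[, 1]
  expect_warning(
    tr <- estimate_transition(A_dup, nets$B),
    "minimum-norm"
  )
  expect_true(all(is.finite(tr$T_full)))
  # wide problem: more TFs than genes warns, then solves minimum-norm
  w <- capture_warnings(
    tr_wide <- estimate_transition(nets$A[1:3, ], nets$B[1:3, ])
  )
  expect_true(any(grepl("underdetermined", w)))
  expect_true(any(grepl("minimum-norm", w)))
  expect_true(all(is.finite(tr_wide$T_full)))
})
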