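# Independent reference implementations used as oracles, plus small fixture
# builders.  Oracles deliberately take the slow, textbook route (lm residuals,
# general-purpose optimization, explicit pseudoinverse) so they share no code
# path with the package.

# Squared partial correlation by residualize-and-correlate with lm().
oracle_sq_pcor <- function(g_i, g_j, conditioners = NULL) {
  if (is.null(conditioners) || NROW(conditioners) == 0L) {
    ri <- g_i - mean(g_i)
    rj <- g_j - mean(g_j)
  } else {
    Z <- as.matrix(conditioners)
    ri <- stats::resid(stats::lm(g_i ~ Z))
    rj <- stats::resid(stats::lm(g_j ~ Z))
  }
  stats::cor(ri, rj)^2
}

# Penalized logistic regression solved by BFGS on the exact objective
#   -loglik + (lambda/2) * ||beta[-1]||^2
# over standardized predictors, as an independent check on the IRLS fit.
# Returns the fitted probabilities.
oracle_penalized_logistic <- function(Z, y, lambda = 1e-6) {
  Zs <- scale(Z)
  Zs[, attr(Zs, "scaled:scale") == 0] <- 0
  X <- cbind(1, Zs)
  pen <- c(0, rep(lambda, ncol(Zs)))
  fn <- function(b) {
    eta <- drop(X %*% b)
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
      0.5 * sum(pen * b^2)
  }
  gr <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    drop(crossprod(X, mu - y)) + pen * b
  }
  b0 <- c(stats::qlogis(mean(y)), numeric(ncol(Zs)))
  # near-separated responses need a generous budget to reach the optimum
  opt <- stats::optim(b0, fn, gr,
    method = "BFGS",
    control = list(maxit = 100000, reltol = 1e-16)
  )
  stats::plogis(drop(X %*% opt$par))
}

# Moore-Penrose pseudoinverse through SVD.
oracle_pinv <- function(A) {
  s <- svd(A)
  pos <- s$d > max(dim(A)) * .Machine$double.eps * s$d[[1L]]
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Random full-column-rank network pair for transition tests.
random_networks <- function(p, m, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(p * m), p, m,
    dimnames = list(sprintf("G%03d", seq_len(p)), sprintf("TF%02d", seq_len(m)))
  )
  B <- matrix(stats::runif(p * m), p, m, dimnames = dimnames(A))
  list(A = A, B = B)
}

# Write a small expression + phenotype + prior fixture to temp files.
write_tiny_inputs <- function(dir = NULL, n_control = 3L, n_case = 3L) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  genes <- c("G1", "G2", "G3", "TFA", "TFB")
  samples <- sprintf("S%d", seq_len(n_control + n_case))
  set.seed(99)
  vals <- matrix(round(stats::rnorm(length(genes) * length(samples)), 4),
    length(genes),
    dimnames = list(genes, samples)
  )
  expr_path <- file.path(dir, "expr.tsv")
  utils::write.table(
    cbind(gene = genes, as.data.frame(vals)),
    expr_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  pheno_path <- file.path(dir, "pheno.tsv")
  utils::write.table(
    data.frame(
      sample = samples,
      group = rep(c("control", "case"), c(n_control, n_case))
    ),
    pheno_path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  prior_path <- file.path(dir, "prior.tsv")
  writeLines(
    c(
      "TFA\tG1\t1", "TFA\tG2\t1", "TFB\tG2\t1", "TFB\tG3\t1"
    ),
    prior_path
  )
  list(expr = expr_path, pheno = pheno_path, prior = prior_path, dir = dir)
}
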