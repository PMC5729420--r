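# State-specific bipartite network inference: direct (squared partial
# correlation) and indirect (logistic regression) evidence, combined by a
# rank-based weighted sum.

#' Direct evidence: squared partial correlations
#'
#' For every (gene j, TF i) pair, computes the squared partial correlation
#' between the TF's encoding-gene expression and the gene's expression,
#' conditioning on the expression of the gene's other motif-predicted
#' regulators (the TFs with a motif for gene j, excluding TF i).  With an
#' empty conditioning set this is the squared Pearson correlation.  Both
#' vectors are residualized on an intercept plus the conditioning block by
#' least squares and the residuals' Pearson correlation is squared; when the
#' conditioning block is rank-deficient or wider than n-2 the projection
#' residuals (those of the minimum-norm solution) are used and a warning
#' counts the affected genes.  A numerically zero-variance residual yields
#' entry 0 (no evidence) rather than NaN.
#'
#' Evidence is produced genome-wide for all pairs, motif or not.
#'
#' @param expr_subset numeric genes-by-samples matrix for one phenotype; must
#'   contain a row for every prior gene and TF, and at least 3 samples.
#' @param prior a harmonized [motif_prior()].
#' @return numeric p-by-m matrix with entries in `[0, 1]`.
#' @export
direct_evidence <- function(expr_subset, prior) {
  stopifnot(inherits(prior, "motif_prior"))
  expr_subset <- as.matrix(expr_subset)
  if (ncol(expr_subset) < 3L) {
    stop("need at least 3 samples", call. = FALSE)
  }
  missing <- setdiff(
    union(prior$gene_ids, prior$tf_ids),
    rownames(expr_subset)
  )
  if (length(missing)) {
    stop(
      "expression rows missing for: ",
      paste(utils::head(missing, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  .direct_evidence_mat(expr_subset, prior$M)
}

.direct_evidence_mat <- function(E, M) {
  genes <- rownames(M)
  tfs <- colnames(M)
  n <- ncol(E)
  # Center once; with centered data the intercept drops out and every
  # residualization reduces to cross-product algebra on tiny matrices.
  X <- t(E[tfs, , drop = FALSE])
  X <- sweep(X, 2L, colMeans(X))
  G <- t(E[genes, , drop = FALSE])
  G <- sweep(G, 2L, colMeans(G))
  p <- ncol(G)
  m <- ncol(X)
  CXX <- crossprod(X) # m x m
  CXG <- crossprod(X, G) # m x p
  ssX <- diag(CXX)
  ssG <- colSums(G^2)
  D <- matrix(0, p, m, dimnames = list(genes, tfs))

  # Residual cross-moments after projecting out the conditioning block C:
  # <u, v | C> = <u, v> - <u, X_C> S^- <X_C, v>, with S = <X_C, X_C> and S^-
  # its (pseudo-)inverse.  The projection residual is unique even when S is
  # singular, so the minimum-norm solution needs no special-casing beyond
  # the pseudo-inverse.  `ill` reports whether S lost rank.
  block_r2 <- function(C, js, is) {
    cross <- CXG[is, js, drop = FALSE] # |is| x |js|
    ssg <- ssG[js]
    ssx <- ssX[is]
    rank_ok <- TRUE
    if (length(C)) {
      S <- CXX[C, C, drop = FALSE]
      eg <- eigen(S, symmetric = TRUE)
      pos <- eg$values > length(C) * .Machine$double.eps * max(eg$values, 0)
      rank_ok <- sum(pos) == length(C)
      Vp <- eg$vectors[, pos, drop = FALSE]
      apply_pinv <- function(Q) {
        Vp %*% (crossprod(Vp, Q) / eg$values[pos])
      }
      Qg <- CXG[C, js, drop = FALSE]
      Qx <- CXX[C, is, drop = FALSE]
      Bg <- apply_pinv(Qg)
      cross <- cross - crossprod(Qx, Bg)
      ssg <- ssg - colSums(Qg * Bg)
      ssx <- ssx - colSums(Qx * apply_pinv(Qx))
    }
    # residual variance below ~1e-12 of the centered original is noise
    dead_g <- ssg <= ssG[js] * 1e-12
    dead_x <- ssx <= ssX[is] * 1e-12
    r2 <- t(cross)^2 / outer(ssg, ssx) # |js| x |is|
    r2[!is.finite(r2)] <- 0
    r2[dead_g, ] <- 0
    r2[, dead_x] <- 0
    list(r2 = pmin(r2, 1), rank_ok = rank_ok)
  }

  # Genes sharing a conditioning set share all the linear algebra, so group
  # them by the motif-regulator set.
  keys <- vapply(
    seq_len(p),
    function(j) paste(which(M[j, ] != 0), collapse = ","),
    character(1L)
  )
  grp <- split(seq_len(p), keys)
  n_ill <- 0L

  for (gi in seq_along(grp)) {
    js <- grp[[gi]]
    key <- names(grp)[[gi]]
    C <- if (nzchar(key)) {
      as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
    } else {
      integer(0)
    }
    io <- setdiff(seq_len(m), C)
    ill <- length(C) > n - 2L
    if (length(io)) {
      blk <- block_r2(C, js, io)
      D[js, io] <- blk$r2
      ill <- ill || !blk$rank_ok
    }
    # TFs inside the conditioning set: leave-one-out designs
    for (i in C) {
      blk <- block_r2(setdiff(C, i), js, i)
      D[js, i] <- blk$r2
      ill <- ill || !blk$rank_ok
    }
    if (ill) n_ill <- n_ill + length(js)
  }
  if (n_ill > 0L) {
    warning(
      "conditioning block rank-deficient or wider than n-2 for ", n_ill,
      " gene(s); minimum-norm residualization used",
      call. = FALSE
    )
  }
  D
}

#' Indirect evidence: per-TF logistic regression on expression profiles
#'
#' For each TF, fits one logistic regression whose binary response is the
#' TF's motif-prior column over the p genes and whose predictors are the
#' samples: row j of the design is gene j's expression across the N samples
#' of the phenotype (plus an intercept).  The fitted probability that gene j
#' carries the TF's motif is the indirect evidence.  Fitting is by iteratively
#' reweighted least squares with a small quadratic penalty on the
#' non-intercept coefficients (predictors standardized internally), which
#' keeps the fit defined under perfect separation.  An all-0 or all-1
#' response column short-circuits to the constant response mean with a
#' warning.
#'
#' @inheritParams direct_evidence
#' @param penalty ridge penalty on the standardized non-intercept
#'   coefficients (default `1e-6`).
#' @return list with `theta` (p-by-m fitted probabilities in `[0, 1]`) and
#'   `coefficients` ((N+1)-by-m matrix of fitted coefficients on the original
#'   predictor scale, intercept first; `NA` for degenerate columns).
#' @export
indirect_evidence <- function(expr_subset, prior, penalty = 1e-6) {
  stopifnot(inherits(prior, "motif_prior"))
  expr_subset <- as.matrix(expr_subset)
  if (ncol(expr_subset) < 3L) {
    stop("need at least 3 samples", call. = FALSE)
  }
  .indirect_evidence_mat(expr_subset, prior$M, penalty = penalty)
}

.indirect_evidence_mat <- function(E, M, penalty = 1e-6) {
  genes <- rownames(M)
  tfs <- colnames(M)
  Z <- E[genes, , drop = FALSE] # p x N design: samples are predictors
  p <- nrow(Z)
  N <- ncol(Z)
  mu_z <- colMeans(Z)
  sd_z <- sqrt(colSums(sweep(Z, 2L, mu_z)^2) / max(p - 1L, 1L))
  scale_z <- ifelse(sd_z > 0, sd_z, 1)
  Zs <- sweep(sweep(Z, 2L, mu_z), 2L, scale_z, "/")
  X <- cbind(1, Zs)

  m <- ncol(M)
  theta <- matrix(0, p, m, dimnames = list(genes, tfs))
  sample_ids <- colnames(E)
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%d", seq_len(N))
  beta <- matrix(NA_real_, N + 1L, m,
    dimnames = list(c("(Intercept)", sample_ids), tfs)
  )
  degenerate <- character(0)
  for (i in seq_len(m)) {
    y <- M[, i]
    if (all(y == 0) || all(y == 1)) {
      theta[, i] <- mean(y)
      degenerate <- c(degenerate, tfs[[i]])
      next
    }
    fit <- .irls_logistic(X, y, penalty)
    theta[, i] <- fit$mu
    # map standardized-scale coefficients back to the raw predictor scale
    b <- fit$beta
    slopes <- b[-1L] / scale_z
    beta[, i] <- c(b[[1L]] - sum(slopes * mu_z), slopes)
  }
  if (length(degenerate)) {
    warning(
      "constant motif response for TF(s) ",
      paste(degenerate, collapse = ", "),
      "; indirect evidence set to the response mean",
      call. = FALSE
    )
  }
  list(theta = theta, coefficients = beta)
}

# Penalized IRLS (Newton with step halving) for logistic regression;
# `penalty` is the lambda in the objective -loglik + (lambda/2)*sum(beta[-1]^2).
.irls_logistic <- function(X, y, penalty, tol = 1e-10, maxit = 200L) {
  k <- ncol(X)
  pen <- c(0, rep(penalty, k - 1L))
  objective <- function(beta) {
    eta <- drop(X %*% beta)
    # log(1 + exp(eta)) without overflow
    lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    sum(lse - y * eta) + 0.5 * sum(pen * beta^2)
  }
  beta <- numeric(k)
  beta[[1L]] <- stats::qlogis(mean(y))
  f <- objective(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    H <- crossprod(X * sqrt(w))
    diag(H) <- diag(H) + pen
    bnew <- drop(solve(H, crossprod(X, w * z)))
    fnew <- objective(bnew)
    halvings <- 0L
    while (fnew > f + 1e-12 * (1 + abs(f)) && halvings < 30L) {
      bnew <- (beta + bnew) / 2
      fnew <- objective(bnew)
      halvings <- halvings + 1L
    }
    done <- max(abs(bnew - beta)) < tol * (1 + max(abs(bnew)))
    beta <- bnew
    f <- fnew
    if (done) break
  }
  list(beta = beta, mu = stats::plogis(drop(X %*% beta)), iterations = it)
}

#' Combine direct and indirect evidence by rank-weighted sum
#'
#' Within each TF column the p target genes are ranked (ascending: larger
#' evidence gets a larger rank, ties receive the average rank) and ranks are
#' normalized by p so they lie in (0, 1].  The combined weight is
#' `(1 - alpha) * rank_norm(direct) + alpha * rank_norm(indirect)`; `alpha =
#' 0.5` gives direct and indirect evidence equal say.  Because only ranks
#' enter, the result is invariant to any strictly increasing per-column
#' transform of either evidence matrix.
#'
#' @param direct,indirect numeric p-by-m evidence matrices of equal shape.
#' @param alpha weight on the indirect evidence, in `[0, 1]`.
#' @return numeric p-by-m matrix of combined edge weights in (0, 1].
#' @export
combine_evidence <- function(direct, indirect, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
    alpha < 0 || alpha > 1) {
    stop("alpha must be a single number in [0, 1]", call. = FALSE)
  }
  if (!all(dim(direct) == dim(indirect))) {
    stop("evidence matrices must have the same shape", call. = FALSE)
  }
  (1 - alpha) * .rank_norm_cols(direct) + alpha * .rank_norm_cols(indirect)
}

#' Infer one phenotype-specific bipartite TF-gene network
#'
#' Subsets the samples of one state, computes direct (squared partial
#' correlation) and indirect (logistic regression) evidence against the motif
#' prior, and combines them with [combine_evidence()].  Inference is fully
#' deterministic.
#'
#' @param expr a harmonized [expression_dataset()].
#' @param prior the matching harmonized [motif_prior()].
#' @param state `"initial"` or `"final"`.
#' @param alpha weight on indirect evidence (default 0.5, equal contribution).
#' @return Object of class `bipartite_network`: list with `weights` (p-by-m),
#'   `direct`, `indirect`, `coefficients`, `alpha`, `tf_ids`, `gene_ids`,
#'   `state`.
#' @export
infer_network <- function(expr, prior, state = c("initial", "final"),
                          alpha = 0.5) {
  stopifnot(inherits(expr, "expression_dataset"))
  state <- match.arg(state)
  E <- expr$values[, group_samples(expr, state), drop = FALSE]
  d <- direct_evidence(E, prior)
  ind <- indirect_evidence(E, prior)
  w <- combine_evidence(d, ind$theta, alpha)
  structure(
    list(
      weights = w, direct = d, indirect = ind$theta,
      coefficients = ind$coefficients, alpha = alpha,
      tf_ids = prior$tf_ids, gene_ids = prior$gene_ids, state = state
    ),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(
    "bipartite_network (", x$state, "): ", length(x$gene_ids), " genes x ",
    length(x$tf_ids), " TFs, alpha = ", x$alpha, "\n",
    sep = ""
  )
  invisible(x)
}
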