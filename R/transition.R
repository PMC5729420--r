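# Transition-matrix estimation: per-TF-column least squares mapping the
# initial network A onto the final network B under B = A T (+ E).

#' Estimate the TF-by-TF network transition matrix
#'
#' Models the change in each TF's targeting column as a linear combination of
#' all TF columns of the initial network: for TF i, the regression of
#' `b_i - a_i` on the columns of `A` gives column i of the difference matrix
#' `T_diff`, and `T_full = T_diff + I` is the transition matrix of the map
#' `B = A T + E`.  A TF that keeps its targets contributes a column of
#' `T_full` near the unit vector `e_i`; off-diagonal mass signals rewiring.
#'
#' The default (`method = "ols"`, no penalty) solves the normal-equations
#' estimand `(A'A)^{-1} A'(b_i - a_i)` per column, computed through a QR
#' factorization rather than an explicit inverse.  If `A'A` is singular the
#' minimum-norm least-squares solution is returned with a prominent warning.
#' `method = "ridge"` adds `penalty * ||tau||_2^2` (solved by an augmented
#' QR); `method = "lasso"` adds `penalty * ||tau||_1` (cyclic coordinate
#' descent, no intercept, columns not re-standardized), which for large
#' enough penalty yields an exactly sparse transition.
#'
#' @param A,B numeric p-by-m weight matrices (or [infer_network()] results)
#'   for the initial and final states, with matching dimnames.
#' @param method one of `"ols"`, `"ridge"`, `"lasso"`.
#' @param penalty nonnegative penalty weight; must be 0 for `"ols"`.
#' @return Object of class `transition_result`: list with `tf_ids`, `T_full`,
#'   `T_diff` (= `T_full - I`), `residuals` (p-by-m error matrix `E`),
#'   `method`, `penalty`.
#' @export
estimate_transition <- function(A, B, method = c("ols", "ridge", "lasso"),
                                penalty = 0) {
  method <- match.arg(method)
  if (inherits(A, "bipartite_network")) A <- A$weights
  if (inherits(B, "bipartite_network")) B <- B$weights
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) {
    stop("A and B must have the same shape", call. = FALSE)
  }
  if (anyNA(A) || anyNA(B) || !all(is.finite(A)) || !all(is.finite(B))) {
    stop("A and B must be finite without missing values", call. = FALSE)
  }
  if (!is.numeric(penalty) || length(penalty) != 1L || penalty < 0) {
    stop("penalty must be a single nonnegative number", call. = FALSE)
  }
  if (method == "ols" && penalty != 0) {
    stop("penalty must be 0 for method = 'ols'", call. = FALSE)
  }
  p <- nrow(A)
  m <- ncol(A)
  if (p < m) {
    warning("fewer genes (", p, ") than TFs (", m,
      "); the regression is underdetermined",
      call. = FALSE
    )
  }
  tf_ids <- colnames(A)
  if (is.null(tf_ids)) tf_ids <- paste0("TF", seq_len(m))
  Y <- B - A

  T_diff <- switch(method,
    ols = {
      qa <- qr(A)
      if (qa$rank < m) {
        warning(
          "A'A is singular (rank ", qa$rank, " < ", m,
          "); returning the minimum-norm least-squares transition",
          call. = FALSE
        )
        .pinv_solve(A, Y)
      } else {
        qr.coef(qa, Y)
      }
    },
    ridge = {
      aug <- rbind(A, sqrt(penalty) * diag(m))
      qr.coef(qr(aug), rbind(Y, matrix(0, m, m)))
    },
    lasso = {
      out <- matrix(0, m, m)
      for (i in seq_len(m)) out[, i] <- .lasso_cd(A, Y[, i], penalty)
      out
    }
  )
  dimnames(T_diff) <- list(tf_ids, tf_ids)
  T_full <- T_diff + diag(m)
  dimnames(T_full) <- dimnames(T_diff)
  E <- Y - A %*% T_diff
  dimnames(E) <- list(rownames(A), tf_ids)
  structure(
    list(
      tf_ids = tf_ids, T_full = T_full, T_diff = T_diff,
      residuals = E, method = method, penalty = penalty
    ),
    class = "transition_result"
  )
}

# Cyclic coordinate descent for  ||y - A b||_2^2 + lambda * ||b||_1 .
.lasso_cd <- function(A, y, lambda, tol = 1e-10, maxit = 10000L) {
  m <- ncol(A)
  ss <- colSums(A^2)
  beta <- numeric(m)
  r <- y
  half <- lambda / 2
  for (it in seq_len(maxit)) {
    delta <- 0
    for (k in seq_len(m)) {
      if (ss[[k]] == 0) next
      bk <- beta[[k]]
      rho <- sum(A[, k] * r) + ss[[k]] * bk
      bnew <- sign(rho) * max(abs(rho) - half, 0) / ss[[k]]
      if (bnew != bk) {
        r <- r - A[, k] * (bnew - bk)
        delta <- max(delta, abs(bnew - bk))
        beta[[k]] <- bnew
      }
    }
    if (delta < tol) break
  }
  beta
}

#' @export
print.transition_result <- function(x, ...) {
  m <- length(x$tf_ids)
  cat(
    "transition_result: ", m, " x ", m, " (", x$method,
    if (x$penalty > 0) paste0(", penalty = ", x$penalty) else "",
    "), max |off-diagonal| = ",
    format(max(abs(x$T_full - diag(diag(x$T_full)))), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Audit the equivalence of the two transition regressions
#'
#' The transition matrix can be written either as the direct regression of
#' the final columns `b_i` on `A`, or as the difference regression of
#' `b_i - a_i` on `A` plus the identity.  When `A` has full column rank the
#' two agree exactly (the projection of `a_i` onto the column space of `A`
#' has coefficient vector `e_i`); this self-test verifies that identity
#' numerically.
#'
#' @param A,B numeric p-by-m matrices; `A` should have full column rank.
#' @param tol maximum tolerated absolute discrepancy.
#' @return `TRUE`/`FALSE`, or `NA` (with a warning) when `A` is
#'   rank-deficient and the identity is not guaranteed.
#' @export
equivalence_check <- function(A, B, tol = 1e-8) {
  if (inherits(A, "bipartite_network")) A <- A$weights
  if (inherits(B, "bipartite_network")) B <- B$weights
  qa <- qr(A)
  if (qa$rank < ncol(A)) {
    warning("A is rank-deficient; equivalence check skipped", call. = FALSE)
    return(NA)
  }
  T_direct <- qr.coef(qa, B)
  T_from_diff <- qr.coef(qa, B - A) + diag(ncol(A))
  max(abs(T_direct - T_from_diff)) < tol
}
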