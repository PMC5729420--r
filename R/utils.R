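# Internal numerical helpers.

# Minimum-norm least-squares solve of X %*% beta = Y via SVD (Moore-Penrose).
.pinv_solve <- function(X, Y) {
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) {
    return(matrix(0, ncol(X), NCOL(Y)))
  }
  s$v[, pos, drop = FALSE] %*%
    ((crossprod(s$u[, pos, drop = FALSE], Y)) / s$d[pos])
}

# Column-wise ascending ranks (average ties) normalized by the number of
# rows, so each column lies in (0, 1].
.rank_norm_cols <- function(x) {
  p <- nrow(x)
  out <- apply(x, 2L, rank, ties.method = "average") / p
  # apply() drops dimensions for single-row input
  if (!is.matrix(out)) out <- matrix(out, nrow = p, dimnames = dimnames(x))
  out
}

# Deterministic child seeds for permutation k = 1..n derived from a master
# seed, so execution order (serial or parallel) cannot change results.
# Kept below 2^31 - 1 (R integers are 32-bit).
.derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Locale-independent (C byte order) sort for deterministic harmonization.
.sort_c <- function(x) sort(x, method = "radix")

.is_whole <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
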