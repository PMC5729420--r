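# Differential TF involvement and its permutation-based calibration.

#' Differential transcription factor involvement (dTFI)
#'
#' For each TF j (column of the transition matrix), the fraction of the
#' column's sum of squares lying off the diagonal:
#' `dTFI_j = sum_{i != j} tau_{i,j}^2 / sum_i tau_{i,j}^2`.
#' An identity column (TF keeps its targets) scores 0; a column whose mass
#' sits entirely off the diagonal scores 1.  Columns with zero sum of squares
#' return 0 with a warning.
#'
#' @param T_full square numeric transition matrix (or a
#'   [estimate_transition()] result, whose `T_full` is used).
#' @return numeric vector of length m in `[0, 1]`, named by TF.
#' @export
dtfi <- function(T_full) {
  if (inherits(T_full, "transition_result")) T_full <- T_full$T_full
  T_full <- as.matrix(T_full)
  if (nrow(T_full) != ncol(T_full)) {
    stop("transition matrix must be square", call. = FALSE)
  }
  ss <- colSums(T_full^2)
  out <- (ss - diag(T_full)^2) / ss
  zero <- ss == 0
  if (any(zero)) {
    warning(sum(zero), " transition column(s) with zero sum of squares; ",
      "dTFI set to 0",
      call. = FALSE
    )
    out[zero] <- 0
  }
  out <- pmin(pmax(out, 0), 1)
  names(out) <- colnames(T_full)
  out
}

# One full observed-pipeline evaluation on plain matrices: two networks,
# transition, dTFI.  `is_final` flags the samples of the final state.
.dtfi_once <- function(values, M, is_final, alpha, method, penalty) {
  EA <- values[, !is_final, drop = FALSE]
  EB <- values[, is_final, drop = FALSE]
  wA <- combine_evidence(
    .direct_evidence_mat(EA, M),
    .indirect_evidence_mat(EA, M)$theta, alpha
  )
  wB <- combine_evidence(
    .direct_evidence_mat(EB, M),
    .indirect_evidence_mat(EB, M)$theta, alpha
  )
  dtfi(estimate_transition(wA, wB, method = method, penalty = penalty))
}

#' Permutation null distribution of dTFI
#'
#' Shuffles the sample-to-phenotype labels (preserving the two group sizes)
#' and reruns the entire pipeline — both network inferences, the transition
#' regression and dTFI — once per permutation, so the null captures the
#' variability of network inference itself.  Each permutation uses a child
#' seed derived deterministically from `seed`, making the result independent
#' of execution order; `workers > 1` forks over permutations without changing
#' any number.
#'
#' @param expr harmonized [expression_dataset()].
#' @param prior harmonized [motif_prior()].
#' @param alpha evidence weight passed to [combine_evidence()].
#' @param method,penalty passed to [estimate_transition()].
#' @param n_perm number of permutations (default 400; at least 2).
#' @param seed master RNG seed.
#' @param workers parallel workers over permutations (forked; numeric output
#'   is identical for any value).
#' @return numeric `n_perm`-by-m matrix of null dTFI values, TF columns.
#' @export
permutation_null <- function(expr, prior, alpha = 0.5, method = "ols",
                             penalty = 0, n_perm = 400L, seed = 1L,
                             workers = 1L) {
  stopifnot(
    inherits(expr, "expression_dataset"),
    inherits(prior, "motif_prior")
  )
  if (!.is_whole(n_perm) || n_perm < 2) {
    stop("n_perm must be an integer >= 2 (the null SD is undefined below 2)",
      call. = FALSE
    )
  }
  n_perm <- as.integer(n_perm)
  values <- expr$values
  is_final <- expr$groups == expr$group_labels[["final"]]
  n <- length(is_final)
  seeds <- .derive_seeds(seed, n_perm)

  one_perm <- function(k) {
    set.seed(seeds[[k]])
    perm_final <- is_final[sample.int(n)]
    .dtfi_once(values, prior$M, perm_final, alpha, method, penalty)
  }
  rows <- if (workers > 1L) {
    parallel::mclapply(seq_len(n_perm), one_perm, mc.cores = workers)
  } else {
    lapply(seq_len(n_perm), one_perm)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Significance of observed dTFI against the permutation null
#'
#' Per TF, a z-score `(observed - null_mean) / null_sd` (sample SD, n-1
#' denominator) is converted to a one-sided upper-tail normal p-value
#' `1 - Phi(z)`; excess dTFI is the signal of interest and dTFI is bounded
#' below, so the lower tail carries no evidence.  False discovery rates are
#' Benjamini-Hochberg step-up across the m TFs.  TFs whose null SD is zero
#' get p = 1 with a warning.
#'
#' @param observed numeric vector of m observed dTFI values (named by TF).
#' @param null numeric `n_perm`-by-m matrix from [permutation_null()].
#' @param seed optional seed to record in the table's attributes.
#' @return Object of class `dtfi_table` (a data.frame) with columns `tf`,
#'   `dtfi`, `null_mean`, `null_sd`, `z`, `p_value`, `fdr`, in the input TF
#'   order; attributes `n_permutations` and `seed`.
#' @export
significance <- function(observed, null, seed = NA_integer_) {
  null <- as.matrix(null)
  if (length(observed) != ncol(null)) {
    stop("observed length and null columns disagree", call. = FALSE)
  }
  if (nrow(null) < 2L) {
    stop("need at least 2 permutations to estimate a null SD", call. = FALSE)
  }
  tf <- names(observed)
  if (is.null(tf)) tf <- colnames(null)
  if (is.null(tf)) tf <- paste0("TF", seq_along(observed))
  null_mean <- colMeans(null)
  null_sd <- apply(null, 2L, stats::sd)
  z <- (unname(observed) - null_mean) / null_sd
  p <- stats::pnorm(z, lower.tail = FALSE)
  flat <- null_sd == 0
  if (any(flat)) {
    warning(sum(flat), " TF(s) with zero null SD; p set to 1", call. = FALSE)
    z[flat] <- NA_real_
    p[flat] <- 1
  }
  out <- data.frame(
    tf = tf,
    dtfi = unname(observed),
    null_mean = unname(null_mean),
    null_sd = unname(null_sd),
    z = unname(z),
    p_value = unname(p),
    fdr = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  attr(out, "n_permutations") <- nrow(null)
  attr(out, "seed") <- seed
  class(out) <- c("dtfi_table", "data.frame")
  out
}

#' @export
print.dtfi_table <- function(x, ...) {
  cat(
    "dtfi_table: ", nrow(x), " TFs, ",
    attr(x, "n_permutations"), " permutations\n",
    sep = ""
  )
  ord <- order(-x$dtfi)
  print.data.frame(x[ord, , drop = FALSE], row.names = FALSE, digits = 4)
  invisible(x)
}
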