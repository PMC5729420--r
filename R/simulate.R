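# Synthetic two-group expression data with a known motif prior and known
# TF-target rewiring, for end-to-end validation of driver recovery.

#' Simulate two-group expression data from a known regulatory model
#'
#' Generates a linear TF-to-gene regulatory model in two states.  The first
#' `m` genes encode the TFs and their expression is i.i.d. standard normal
#' per sample; every other gene is assigned `targets_per_gene` regulators
#' uniformly at random and its expression is
#' `effect_size * sum(regulator TF expression) + N(0, noise_sd)` per sample.
#' Between states, `n_drivers` disjoint TF pairs rewire: `"swap"` exchanges
#' the two TFs' entire target columns, `"transfer"` moves half of the first
#' TF's targets to the second.  The motif prior handed to the pipeline
#' reflects the initial state only — as in real use, one static motif map
#' serves both phenotypes and the rewiring is visible only through
#' expression.
#'
#' Defaults describe a moderately sized two-group study with a clear but
#' noisy signal (signal-to-noise `effect_size / noise_sd = 2`, 30 samples per
#' group).
#'
#' @param p total number of genes, including the `m` TF-encoding genes.
#' @param m number of transcription factors (`p > m`).
#' @param targets_per_gene motif regulators assigned to each non-TF gene
#'   (`<= m`).
#' @param n_per_group length-2 integer vector: samples in the initial and
#'   final groups.
#' @param effect_size regulatory weight of each TF on its targets.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   target genes.
#' @param n_drivers number of rewired TF *pairs* (0 for a null dataset;
#'   requires `m >= 2 * n_drivers`).
#' @param rewire_mode `"swap"` or `"transfer"`.
#' @param seed RNG seed; the whole output is reproducible from it.
#' @return list with `expr` (an [expression_dataset()], groups labeled
#'   `"control"` = initial and `"case"` = final), `prior` (the initial-state
#'   [motif_prior()]), and `truth` (class `synthetic_truth`: `W_initial`,
#'   `W_final`, `driver_tfs`, `driver_pairs`, the generator parameters and
#'   `seed`).
#' @export
simulate_regulatory_data <- function(p = 200L, m = 10L, targets_per_gene = 2L,
                                     n_per_group = c(30L, 30L),
                                     effect_size = 1, noise_sd = 0.5,
                                     n_drivers = 1L,
                                     rewire_mode = c("swap", "transfer"),
                                     seed = 1L) {
  rewire_mode <- match.arg(rewire_mode)
  if (!.is_whole(p) || !.is_whole(m) || p <= m || m < 2L) {
    stop("need integer sizes with p > m >= 2", call. = FALSE)
  }
  if (!.is_whole(targets_per_gene) || targets_per_gene < 1L ||
    targets_per_gene > m) {
    stop("targets_per_gene must be in 1..m", call. = FALSE)
  }
  if (!.is_whole(n_drivers) || n_drivers < 0L || 2L * n_drivers > m) {
    stop("need m >= 2 * n_drivers with n_drivers >= 0", call. = FALSE)
  }
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 2L || any(n_per_group < 3L)) {
    stop("n_per_group must give two group sizes of at least 3", call. = FALSE)
  }
  if (noise_sd <= 0 || effect_size <= 0) {
    stop("effect_size and noise_sd must be positive", call. = FALSE)
  }
  set.seed(seed)

  tf_ids <- sprintf("TF%02d", seq_len(m))
  target_ids <- sprintf("G%04d", seq_len(p - m))
  gene_ids <- c(tf_ids, target_ids)

  M <- matrix(0, p, m, dimnames = list(gene_ids, tf_ids))
  for (g in target_ids) {
    M[g, sample.int(m, targets_per_gene)] <- 1
  }
  W_initial <- effect_size * M

  driver_pairs <- list()
  W_final <- W_initial
  if (n_drivers > 0L) {
    chosen <- sample.int(m, 2L * n_drivers)
    for (d in seq_len(n_drivers)) {
      a <- chosen[[2L * d - 1L]]
      b <- chosen[[2L * d]]
      driver_pairs[[d]] <- c(tf_ids[[a]], tf_ids[[b]])
      if (rewire_mode == "swap") {
        W_final[, c(a, b)] <- W_initial[, c(b, a)]
      } else {
        targets_a <- which(W_initial[, a] != 0)
        moved <- targets_a[seq_len(ceiling(length(targets_a) / 2))]
        W_final[moved, a] <- 0
        W_final[moved, b] <- effect_size
      }
    }
  }
  driver_tfs <- tf_ids[which(colSums(W_initial != W_final) > 0)]

  sample_ids <- sprintf("S%03d", seq_len(sum(n_per_group)))
  groups <- stats::setNames(
    rep(c("control", "case"), n_per_group),
    sample_ids
  )
  draw_group <- function(W, n) {
    tf_expr <- matrix(stats::rnorm(m * n), m, n)
    vals <- W %*% tf_expr +
      noise_sd * matrix(stats::rnorm(p * n), p, n)
    vals[seq_len(m), ] <- tf_expr # TF genes are measured directly
    vals
  }
  values <- cbind(
    draw_group(W_initial, n_per_group[[1L]]),
    draw_group(W_final, n_per_group[[2L]])
  )
  dimnames(values) <- list(gene_ids, sample_ids)

  truth <- structure(
    list(
      W_initial = W_initial, W_final = W_final,
      driver_tfs = driver_tfs, driver_pairs = driver_pairs,
      rewire_mode = rewire_mode, effect_size = effect_size,
      noise_sd = noise_sd, n_per_group = n_per_group,
      targets_per_gene = targets_per_gene, seed = seed
    ),
    class = "synthetic_truth"
  )
  list(
    expr = expression_dataset(values, groups, initial_label = "control"),
    # built directly: the generator keeps every TF column, even one that
    # drew no targets, so the prior always matches the truth matrices
    prior = structure(
      list(M = M, tf_ids = tf_ids, gene_ids = gene_ids),
      class = "motif_prior"
    ),
    truth = truth
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(
    "synthetic_truth: ", nrow(x$W_initial), " genes x ", ncol(x$W_initial),
    " TFs, ", x$rewire_mode, "-rewired drivers: ",
    if (length(x$driver_tfs)) paste(x$driver_tfs, collapse = ", ") else "none",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Score driver-TF recovery of a dTFI table against the simulated truth
#'
#' Reports where the true driver TFs fall in the descending dTFI ordering and
#' whether all of them land in the top `k` positions, where `k` is the number
#' of driver TFs (two per rewired pair).
#'
#' @param dtfi_table a [significance()] result (or any data.frame with `tf`
#'   and `dtfi` columns) over the same TF universe as `truth`.
#' @param truth the `truth` element of [simulate_regulatory_data()].
#' @return list with `driver_ranks` (named integer vector), `top_k`,
#'   `recovered` (`TRUE`/`FALSE`, or `NA` for a driver-free null dataset).
#' @export
score_recovery <- function(dtfi_table, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!all(truth$driver_tfs %in% dtfi_table$tf)) {
    stop("dTFI table does not cover all driver TFs", call. = FALSE)
  }
  if (length(truth$driver_tfs) == 0L) {
    return(list(
      driver_ranks = integer(0), top_k = 0L,
      recovered = NA
    ))
  }
  ord <- dtfi_table$tf[order(-dtfi_table$dtfi)]
  ranks <- match(truth$driver_tfs, ord)
  names(ranks) <- truth$driver_tfs
  k <- length(truth$driver_tfs)
  list(
    driver_ranks = ranks,
    top_k = k,
    recovered = all(ranks <= k)
  )
}
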