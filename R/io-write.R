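# TSV writers/readers for the pipeline artifacts.  Floats are printed with
# 17 significant digits so a write/read round trip reproduces every value to
# well below 1e-12.

.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

.check_writable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("cannot write '", path, "': directory does not exist", call. = FALSE)
  }
  invisible(path)
}

#' Write / read a bipartite network as a TSV edge table
#'
#' One row per (tf, gene) pair with columns `tf`, `gene`, `weight`,
#' `direct`, `indirect`.
#'
#' @param net a `bipartite_network` from [infer_network()].
#' @param path output file path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `bipartite_network` (without refit coefficients).
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "bipartite_network"))
  .check_writable(path)
  tf <- rep(net$tf_ids, each = length(net$gene_ids))
  gene <- rep(net$gene_ids, times = length(net$tf_ids))
  tab <- data.frame(
    tf = tf,
    gene = gene,
    weight = .fmt_num(as.vector(net$weights)),
    direct = .fmt_num(as.vector(net$direct)),
    indirect = .fmt_num(as.vector(net$indirect)),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  tfs <- unique(tab$tf)
  genes <- unique(tab$gene)
  shape <- function(col) {
    matrix(as.numeric(col),
      nrow = length(genes), ncol = length(tfs),
      dimnames = list(genes, tfs)
    )
  }
  structure(
    list(
      weights = shape(tab$weight), direct = shape(tab$direct),
      indirect = shape(tab$indirect), coefficients = NULL,
      alpha = NA_real_, tf_ids = tfs, gene_ids = genes, state = NA_character_
    ),
    class = "bipartite_network"
  )
}

#' Write / read a transition matrix as a labeled TSV
#'
#' The m-by-m matrix is written with a TF header row and a leading TF id
#' column.  By default `T_full` is written; `what = "diff"` writes the
#' difference form `T_full - I`.
#'
#' @param tr a [estimate_transition()] result (or a plain labeled matrix).
#' @param path output file path.
#' @param what `"full"` or `"diff"`.
#' @return `write_transition()` returns `path` invisibly; `read_transition()`
#'   returns the labeled numeric matrix.
#' @export
write_transition <- function(tr, path, what = c("full", "diff")) {
  what <- match.arg(what)
  Tm <- if (inherits(tr, "transition_result")) {
    if (what == "full") tr$T_full else tr$T_diff
  } else {
    as.matrix(tr)
  }
  .check_writable(path)
  out <- cbind(
    tf = rownames(Tm),
    as.data.frame(matrix(.fmt_num(Tm), nrow(Tm),
      dimnames = dimnames(Tm)
    ), check.names = FALSE)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition
#' @export
read_transition <- function(path) {
  tab <- utils::read.delim(path,
    header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  Tm <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(Tm) <- "double"
  rownames(Tm) <- tab[[1L]]
  Tm
}

#' Write / read a dTFI table as a TSV
#'
#' Columns `tf`, `dtfi`, `null_mean`, `null_sd`, `z`, `p_value`, `fdr`,
#' sorted by descending dTFI.
#'
#' @param tab a `dtfi_table` from [significance()].
#' @param path output file path.
#' @return `write_dtfi()` returns `path` invisibly; `read_dtfi()` returns a
#'   `dtfi_table` (sorted as written; permutation count/seed attributes are
#'   not stored in the file).
#' @export
write_dtfi <- function(tab, path) {
  stopifnot(is.data.frame(tab))
  .check_writable(path)
  tab <- tab[order(-tab$dtfi), , drop = FALSE]
  out <- data.frame(
    tf = tab$tf,
    dtfi = .fmt_num(tab$dtfi),
    null_mean = .fmt_num(tab$null_mean),
    null_sd = .fmt_num(tab$null_sd),
    z = .fmt_num(tab$z),
    p_value = .fmt_num(tab$p_value),
    fdr = .fmt_num(tab$fdr),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dtfi
#' @export
read_dtfi <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  for (col in c("dtfi", "null_mean", "null_sd", "z", "p_value", "fdr")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  class(tab) <- c("dtfi_table", "data.frame")
  tab
}

#' Write an expression dataset and motif prior in the input dialects
#'
#' Convenience writers matching what [read_expression()] and
#' [read_motif_prior()] read: an expression TSV (gene id column plus sample
#' columns), a two-column phenotype TSV (initial-state label first), and a
#' three-column motif edge list.
#'
#' @param expr an [expression_dataset()].
#' @param path,phenotype_path output paths for the expression matrix and the
#'   phenotype map.
#' @return the (first) path, invisibly.
#' @export
write_expression <- function(expr, path, phenotype_path) {
  stopifnot(inherits(expr, "expression_dataset"))
  .check_writable(path)
  .check_writable(phenotype_path)
  out <- cbind(
    gene = rownames(expr$values),
    as.data.frame(matrix(.fmt_num(expr$values), nrow(expr$values),
      dimnames = dimnames(expr$values)
    ), check.names = FALSE)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  # initial-state samples first so first appearance defines the initial label
  ord <- order(expr$groups != expr$group_labels[["initial"]])
  utils::write.table(
    data.frame(
      sample = names(expr$groups)[ord],
      group = unname(expr$groups)[ord]
    ),
    phenotype_path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_expression
#' @param prior a [motif_prior()].
#' @export
write_motif_prior <- function(prior, path) {
  stopifnot(inherits(prior, "motif_prior"))
  .check_writable(path)
  idx <- which(prior$M != 0, arr.ind = TRUE)
  tab <- data.frame(
    tf = prior$tf_ids[idx[, 2L]],
    gene = prior$gene_ids[idx[, 1L]],
    value = 1L
  )
  tab <- tab[order(tab$tf, tab$gene, method = "radix"), , drop = FALSE]
  utils::write.table(tab, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
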