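#' Construct a binary motif prior
#'
#' A motif prior is a binary genes-by-TFs matrix `M` marking, for each gene,
#' which transcription factors have a sequence binding motif in its promoter
#' region.  It defines each gene's candidate regulator set and is input
#' evidence, never inferred.
#'
#' @param M numeric matrix with gene rownames and TF colnames; entries are
#'   coerced to 0/1 (any nonzero becomes 1).
#' @return An object of class `motif_prior`: list with `M` (binary matrix),
#'   `tf_ids`, `gene_ids`.
#' @seealso [read_motif_prior()], [harmonize()]
#' @export
motif_prior <- function(M) {
  M <- as.matrix(M)
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    stop("motif matrix needs gene rownames and TF colnames", call. = FALSE)
  }
  if (anyNA(M) || !is.numeric(M)) {
    stop("motif matrix must be numeric without missing values", call. = FALSE)
  }
  M <- (M != 0) + 0
  empty <- colSums(M) == 0
  if (any(empty)) {
    warning(
      "dropped TF(s) with no motif targets: ",
      paste(colnames(M)[empty], collapse = ", "),
      call. = FALSE
    )
    M <- M[, !empty, drop = FALSE]
  }
  if (ncol(M) == 0L) {
    stop("motif prior has no TFs with targets", call. = FALSE)
  }
  structure(
    list(M = M, tf_ids = colnames(M), gene_ids = rownames(M)),
    class = "motif_prior"
  )
}

#' @export
print.motif_prior <- function(x, ...) {
  cat(
    "motif_prior: ", length(x$gene_ids), " genes x ", length(x$tf_ids),
    " TFs, ", sum(x$M), " motif edges\n",
    sep = ""
  )
  invisible(x)
}

#' Read a motif prior from a TF-gene edge list
#'
#' Accepts a two-column (tf id, gene id) or three-column (tf id, gene id,
#' value) tab-separated file without a header.  Any nonzero value marks a
#' motif; duplicate (tf, gene) rows collapse by logical OR.
#'
#' @param path edge-list TSV path.
#' @return A [motif_prior()].
#' @export
read_motif_prior <- function(path) {
  tab <- utils::read.delim(path,
    header = FALSE, sep = "\t",
    stringsAsFactors = FALSE
  )
  if (!ncol(tab) %in% c(2L, 3L)) {
    stop("motif prior must have 2 or 3 columns (tf, gene[, value])",
      call. = FALSE
    )
  }
  tf <- as.character(tab[[1L]])
  gene <- as.character(tab[[2L]])
  if (ncol(tab) == 3L) {
    val <- suppressWarnings(as.numeric(tab[[3L]]))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1L]
      stop("non-numeric motif value at line ", bad, ": '", tab[[3L]][bad],
        "'",
        call. = FALSE
      )
    }
  } else {
    val <- rep(1, length(tf))
  }
  keep <- val != 0
  genes <- unique(gene)
  tfs <- unique(tf)
  M <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  if (any(keep)) {
    M[cbind(
      match(gene[keep], genes),
      match(tf[keep], tfs)
    )] <- 1
  }
  motif_prior(M)
}

#' Harmonize an expression dataset and a motif prior
#'
#' Restricts both inputs to a shared, deterministically ordered universe: the
#' gene universe is every gene with an expression row (genes missing from the
#' prior get an all-zero motif row); the TF set is every prior TF whose
#' encoding gene has an expression row (TFs without expression are dropped
#' with a warning).  Gene and TF orders are sorted byte-wise so repeated runs
#' agree across platforms; harmonization is idempotent.
#'
#' @param expr an [expression_dataset()].
#' @param prior a [motif_prior()].
#' @return list with elements `expr` and `prior`, harmonized.
#' @export
harmonize <- function(expr, prior) {
  stopifnot(inherits(expr, "expression_dataset"), inherits(prior, "motif_prior"))
  genes <- .sort_c(rownames(expr$values))
  tfs <- intersect(prior$tf_ids, genes)
  dropped <- setdiff(prior$tf_ids, tfs)
  if (length(dropped)) {
    warning(
      "dropped ", length(dropped),
      " TF(s) without an expression row: ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(tfs) == 0L) {
    stop("no TF in the prior has an expression row", call. = FALSE)
  }
  tfs <- .sort_c(tfs)
  M <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  shared <- intersect(genes, prior$gene_ids)
  M[shared, ] <- prior$M[shared, tfs, drop = FALSE]

  values <- expr$values[genes, , drop = FALSE]
  out_expr <- expression_dataset(values, expr$groups,
    initial_label = expr$group_labels[["initial"]]
  )
  # Bypass the zero-target TF drop of motif_prior(): a TF whose motif targets
  # all lack expression keeps an all-zero column so downstream evidence still
  # covers it (direct evidence then reduces to marginal correlations).
  out_prior <- structure(
    list(M = M, tf_ids = tfs, gene_ids = genes),
    class = "motif_prior"
  )
  list(expr = out_expr, prior = out_prior)
}
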