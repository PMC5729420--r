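#' Construct an expression dataset with a two-group phenotype assignment
#'
#' Bundles a genes-by-samples real matrix with a mapping of each sample to one
#' of two phenotypic states.  The first state is the "initial" state (the
#' baseline of the transition, e.g. smoker controls) and the second the
#' "final" state (e.g. COPD cases).
#'
#' @param values numeric matrix, genes in rows (unique rownames) and samples
#'   in columns (unique colnames).  Assumed to be on a roughly continuous
#'   (e.g. log-intensity) scale; this is not enforced.
#' @param groups character vector naming each sample's group label, with
#'   `names(groups)` equal to the sample ids (any order).  Exactly two
#'   distinct labels are required and each group needs at least 3 samples.
#' @param initial_label which group label is the initial state.  Defaults to
#'   the label of the first sample (column order of `values`).
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (the matrix), `groups` (named character vector, in column
#'   order), and `group_labels` (named character vector with entries
#'   `initial` and `final`).
#' @seealso [read_expression()] to build one from TSV files.
#' @export
expression_dataset <- function(values, groups, initial_label = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames",
      call. = FALSE
    )
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop(
      "duplicate gene id(s): ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) {
    stop(
      "duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyNA(values)) {
    stop("expression values contain missing entries; drop or impute upstream",
      call. = FALSE
    )
  }
  groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(names(groups))) {
    stop("`groups` must be named by sample id", call. = FALSE)
  }
  missing_pheno <- setdiff(colnames(values), names(groups))
  missing_expr <- setdiff(names(groups), colnames(values))
  if (length(missing_pheno) || length(missing_expr)) {
    stop(
      "sample sets disagree between expression and phenotype; ",
      if (length(missing_pheno)) {
        paste0(
          "no phenotype for: ",
          paste(missing_pheno, collapse = ", "), ". "
        )
      } else "",
      if (length(missing_expr)) {
        paste0(
          "no expression for: ",
          paste(missing_expr, collapse = ", ")
        )
      } else "",
      call. = FALSE
    )
  }
  groups <- groups[colnames(values)]
  labs <- unique(unname(groups))
  if (length(labs) != 2L) {
    stop("exactly two groups required, got ", length(labs), ": ",
      paste(labs, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(initial_label)) initial_label <- labs[[1L]]
  if (!initial_label %in% labs) {
    stop("initial_label '", initial_label, "' is not a group label",
      call. = FALSE
    )
  }
  final_label <- setdiff(labs, initial_label)
  sizes <- table(groups)
  if (any(sizes < 3L)) {
    stop("each group needs at least 3 samples; sizes are ",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      values = values,
      groups = groups,
      group_labels = c(initial = initial_label, final = final_label)
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  sizes <- table(x$groups)
  cat(
    "expression_dataset: ", nrow(x$values), " genes x ",
    ncol(x$values), " samples\n",
    sep = ""
  )
  cat(
    "  initial: ", x$group_labels[["initial"]],
    " (n=", sizes[[x$group_labels[["initial"]]]], ")",
    "   final: ", x$group_labels[["final"]],
    " (n=", sizes[[x$group_labels[["final"]]]], ")\n",
    sep = ""
  )
  invisible(x)
}

#' Sample ids belonging to one state of an expression dataset
#'
#' @param x an `expression_dataset`.
#' @param state `"initial"` or `"final"`.
#' @return character vector of sample ids, in column order.
#' @export
group_samples <- function(x, state = c("initial", "final")) {
  stopifnot(inherits(x, "expression_dataset"))
  state <- match.arg(state)
  names(x$groups)[x$groups == x$group_labels[[state]]]
}

#' Read an expression matrix and its sample phenotype file
#'
#' The expression file is tab-separated with gene ids in the first column and
#' a header row of sample ids.  The phenotype file is a two-column
#' tab-separated file (sample id, group label) without a header; it must
#' contain exactly two distinct labels covering exactly the samples of the
#' expression file.  The label that appears first in the phenotype file is
#' taken as the initial state unless `initial_label` says otherwise.
#'
#' Genes with any missing value are dropped with a warning giving the count;
#' imputation is deliberately out of scope.
#'
#' @param path expression TSV path.
#' @param phenotype_path two-column phenotype TSV path.
#' @param initial_label optional group label to treat as the initial state.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, phenotype_path, initial_label = NULL) {
  tab <- utils::read.delim(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    stringsAsFactors = FALSE
  )
  if (ncol(tab) < 2L) {
    stop("expression file needs a gene id column plus sample columns",
      call. = FALSE
    )
  }
  gene_ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids

  n_na <- sum(!stats::complete.cases(values))
  if (n_na > 0L) {
    warning(
      "dropped ", n_na, " gene(s) with missing expression values",
      call. = FALSE
    )
    values <- values[stats::complete.cases(values), , drop = FALSE]
  }

  ph <- utils::read.delim(phenotype_path,
    header = FALSE, sep = "\t",
    stringsAsFactors = FALSE
  )
  if (ncol(ph) != 2L) {
    stop("phenotype file must have exactly two columns (sample id, group)",
      call. = FALSE
    )
  }
  groups <- stats::setNames(as.character(ph[[2L]]), as.character(ph[[1L]]))
  dup <- names(groups)[duplicated(names(groups))]
  if (length(dup)) {
    stop("duplicate sample id(s) in phenotype file: ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  labs <- unique(unname(groups))
  if (length(labs) != 2L) {
    stop("exactly two groups required, got ", length(labs), ": ",
      paste(labs, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(initial_label)) initial_label <- labs[[1L]]
  expression_dataset(values, groups, initial_label = initial_label)
}
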