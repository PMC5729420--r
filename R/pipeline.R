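# End-to-end pipeline: read + harmonize inputs, infer both state networks,
# estimate the transition, calibrate dTFI by permutation, write artifacts.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline.  The defaults reproduce the
#' method's reference configuration: equal evidence weighting (`alpha =
#' 0.5`), unpenalized normal-equations transition fit, and 400 sample-label
#' permutations.
#'
#' @param alpha weight on indirect evidence, in `[0, 1]`.
#' @param method transition solver: `"ols"`, `"ridge"` or `"lasso"`.
#' @param penalty nonnegative penalty (0 for `"ols"`).
#' @param n_permutations permutations for the dTFI null (default 400).
#' @param seed master RNG seed (default 1).
#' @param initial_label,final_label optional group labels overriding the
#'   phenotype file's first-appearance order.
#' @param workers parallel workers over permutations; never changes numbers.
#' @param emit_null also write the full permutation-null matrix.
#' @param emit_diff also write the difference form of the transition matrix.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.5, method = c("ols", "ridge", "lasso"),
                            penalty = 0, n_permutations = 400L, seed = 1L,
                            initial_label = NULL, final_label = NULL,
                            workers = 1L, emit_null = FALSE,
                            emit_diff = FALSE) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
    alpha < 0 || alpha > 1) {
    stop("alpha must be a single number in [0, 1]", call. = FALSE)
  }
  if (!.is_whole(seed)) stop("seed must be an integer", call. = FALSE)
  structure(
    list(
      alpha = alpha, method = method, penalty = penalty,
      n_permutations = as.integer(n_permutations), seed = as.integer(seed),
      initial_label = initial_label, final_label = final_label,
      workers = as.integer(workers), emit_null = isTRUE(emit_null),
      emit_diff = isTRUE(emit_diff)
    ),
    class = "pipeline_config"
  )
}

#' Run the full pipeline from input files to output artifacts
#'
#' Reads the expression matrix, phenotype map and motif prior, harmonizes
#' them, infers the initial- and final-state networks, estimates the
#' transition matrix, calibrates dTFI against the sample-label permutation
#' null, and writes five artifacts into `out_dir`: `network_initial.tsv`,
#' `network_final.tsv`, `transition.tsv`, `dtfi.tsv` and `manifest.json`
#' (parameters, seed, input checksums, package version).  On any stage
#' failure the partial outputs are removed and the error is re-raised with
#' the stage name.
#'
#' @param expr_path,phenotype_path,prior_path input file paths (see
#'   [read_expression()] and [read_motif_prior()] for the dialects).
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results (`network_initial`,
#'   `network_final`, `transition`, `dtfi_table`, `null`) and `paths` of the
#'   written artifacts.
#' @export
run_pipeline <- function(expr_path, phenotype_path, prior_path, out_dir,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  written <- character(0)
  stage <- "read"
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(msg) {
    message(sprintf(
      "[monster] %-10s %6.1fs  %s",
      stage, proc.time()[["elapsed"]] - t0, msg
    ))
  }
  emit <- function(fun, obj, file, ...) {
    path <- file.path(out_dir, file)
    fun(obj, path, ...)
    written <<- c(written, path)
    path
  }

  result <- tryCatch(
    {
      expr <- read_expression(expr_path, phenotype_path,
        initial_label = config$initial_label
      )
      if (!is.null(config$final_label)) {
        expr <- expression_dataset(expr$values, expr$groups,
          initial_label = setdiff(
            unique(unname(expr$groups)),
            config$final_label
          )
        )
      }
      prior <- read_motif_prior(prior_path)
      h <- harmonize(expr, prior)
      log_stage(sprintf(
        "%d genes x %d samples, %d TFs (initial='%s', final='%s')",
        nrow(h$expr$values), ncol(h$expr$values), length(h$prior$tf_ids),
        h$expr$group_labels[["initial"]], h$expr$group_labels[["final"]]
      ))

      stage <- "infer"
      net_a <- infer_network(h$expr, h$prior, "initial", alpha = config$alpha)
      net_b <- infer_network(h$expr, h$prior, "final", alpha = config$alpha)
      emit(write_network, net_a, "network_initial.tsv")
      emit(write_network, net_b, "network_final.tsv")
      log_stage("both state networks inferred")

      stage <- "transition"
      tr <- estimate_transition(net_a, net_b,
        method = config$method,
        penalty = config$penalty
      )
      emit(write_transition, tr, "transition.tsv")
      if (config$emit_diff) {
        emit(write_transition, tr, "transition_diff.tsv", what = "diff")
      }
      log_stage(sprintf("%d x %d transition (%s)", ncol(tr$T_full),
        ncol(tr$T_full), config$method))

      stage <- "dtfi"
      observed <- dtfi(tr)
      null <- permutation_null(h$expr, h$prior,
        alpha = config$alpha,
        method = config$method, penalty = config$penalty,
        n_perm = config$n_permutations, seed = config$seed,
        workers = config$workers
      )
      tab <- significance(observed, null, seed = config$seed)
      emit(write_dtfi, tab, "dtfi.tsv")
      if (config$emit_null) {
        path <- file.path(out_dir, "dtfi_null.tsv")
        utils::write.table(
          data.frame(apply(null, 2L, .fmt_num), check.names = FALSE),
          path,
          sep = "\t", quote = FALSE, row.names = FALSE
        )
        written <- c(written, path)
      }
      log_stage(sprintf("dTFI over %d permutations", config$n_permutations))

      stage <- "manifest"
      manifest <- list(
        package = "monster",
        version = as.character(utils::packageVersion("monster")),
        parameters = config[c(
          "alpha", "method", "penalty",
          "n_permutations", "seed", "workers"
        )],
        groups = as.list(h$expr$group_labels),
        inputs = list(
          expression = unname(tools::md5sum(expr_path)),
          phenotype = unname(tools::md5sum(phenotype_path)),
          prior = unname(tools::md5sum(prior_path))
        ),
        dimensions = list(
          genes = nrow(h$expr$values),
          samples = ncol(h$expr$values),
          tfs = length(h$prior$tf_ids)
        )
      )
      manifest_path <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest, manifest_path,
        auto_unbox = TRUE,
        pretty = TRUE, digits = NA
      )
      written <- c(written, manifest_path)
      log_stage("manifest written")

      list(
        network_initial = net_a, network_final = net_b, transition = tr,
        dtfi_table = tab, null = null, paths = written
      )
    },
    error = function(e) {
      unlink(written)
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  invisible(result)
}
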