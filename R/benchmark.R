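#' Build the random-signature gene pool from a gene-set collection
#'
#' Union of all set members, deduplicated, restricted to genes measured in
#' the expression matrix, sorted lexicographically. This is the pool from
#' which equally sized random signatures are drawn.
#'
#' @param collection a `gene_set_collection`.
#' @param expr_genes character vector of measured gene symbols (expression
#'   matrix row names).
#' @return Sorted character vector of pool genes, class `signature_pool`.
#' @export
build_gene_pool <- function(collection, expr_genes) {
  stopifnot(inherits(collection, "gene_set_collection"),
            length(collection) > 0L)
  pool <- sort(intersect(unique(canonical_symbol(unlist(collection))),
                         unique(canonical_symbol(expr_genes))))
  if (length(pool) == 0L) {
    stop("no pathway gene is present in the expression matrix")
  }
  structure(pool, class = "signature_pool")
}

#' Benchmark configuration
#'
#' @param n_signatures number of random signatures (study default 1000).
#' @param signature_size genes per signature (study default 76).
#' @param alpha significance threshold for the log-rank p (default 0.05).
#' @param master_seed integer seed; per-draw seeds are `master_seed + i`.
#' @param min_fraction minimum cluster fraction for the dynamic cut.
#' @return List of class `benchmark_config`.
#' @export
benchmark_config <- function(n_signatures = 1000L, signature_size = 76L,
                             alpha = 0.05, master_seed = 1L,
                             min_fraction = 0.125) {
  stopifnot(n_signatures >= 1L, signature_size >= 2L,
            alpha > 0, alpha < 1, min_fraction > 0, min_fraction <= 0.5)
  structure(list(n_signatures = as.integer(n_signatures),
                 signature_size = as.integer(signature_size),
                 alpha = alpha, master_seed = as.integer(master_seed),
                 min_fraction = min_fraction),
            class = "benchmark_config")
}

#' Draw random gene signatures from the pool
#'
#' Each signature is a uniform sample without replacement of
#' `signature_size` genes; draws are independent across signatures (the
#' same signature can recur by chance). The seed of draw i is
#' `master_seed + i`, so results are reproducible and individual draws can
#' be replayed.
#'
#' @param pool a `signature_pool`.
#' @param config a `benchmark_config`.
#' @return List of character vectors, length `n_signatures`.
#' @export
sample_signatures <- function(pool, config) {
  stopifnot(inherits(config, "benchmark_config"))
  if (config$signature_size > length(pool)) {
    stop("signature_size exceeds the pool size")
  }
  lapply(seq_len(config$n_signatures), function(i) {
    set.seed(config$master_seed + i)
    sort(sample(as.character(pool), config$signature_size))
  })
}

#' Run the random-signature prognostic benchmark
#'
#' For each random signature the identical stratification chain used for
#' the original signature is executed (signature subset, correlation
#' distance, complete-linkage clustering, dynamic hybrid cut, log-rank
#' test) and the log-rank p-value recorded. Signatures for which only one
#' cluster is detected carry no testable survival contrast and are scored
#' p = 1 (counted in `n_single_cluster`). Preprocessing (probe collapse,
#' quantile normalization, patient matching) is done once, up front,
#' exactly as for the original signature.
#'
#' @param expr expression matrix.
#' @param survival_data survival annotations (`patient`, `time`, `event`,
#'   optional `subtype`).
#' @param pool a `signature_pool`.
#' @param config a `benchmark_config`.
#' @param original_p log-rank p-value of the original signature (optional;
#'   enables `frac_outperforming`).
#' @param probe_map optional probe -> gene map.
#' @param subtype_filter optional subtype restriction (as in [stratify()]).
#' @param normalize quantile-normalize once before the loop (default TRUE).
#' @return List of class `benchmark_result`: `pvalues`, `neglog10`,
#'   `k_detected`, `n_single_cluster`, `frac_significant`,
#'   `frac_outperforming` (NA without `original_p`), `original_p`,
#'   `config`.
#' @export
run_benchmark <- function(expr, survival_data, pool, config,
                          original_p = NA_real_, probe_map = NULL,
                          subtype_filter = NULL, normalize = TRUE) {
  stopifnot(inherits(config, "benchmark_config"))
  survival_data <- survival_records(records_with_patient(survival_data))
  if (!is.null(subtype_filter)) {
    if (!subtype_filter %in% survival_data$subtype) {
      stop("subtype label not present in annotations: ", subtype_filter)
    }
    survival_data <- survival_data[survival_data$subtype == subtype_filter, ,
                                   drop = FALSE]
  }
  if (!is.null(probe_map)) expr <- collapse_probes(expr, probe_map)
  patients <- intersect(colnames(expr), survival_data$patient)
  expr <- expression_matrix(expr[, patients, drop = FALSE], row_kind = "gene")
  survival_data <-
    survival_data[match(patients, survival_data$patient), , drop = FALSE]
  if (normalize && ncol(expr) >= 2L) expr <- quantile_normalize(expr)
  missing_pool <- setdiff(as.character(pool), rownames(expr))
  if (length(missing_pool) > 0L) {
    stop("pool gene(s) absent from the expression matrix: ",
         paste(utils::head(missing_pool, 5L), collapse = ", "))
  }
  signatures <- sample_signatures(pool, config)
  pvalues <- numeric(config$n_signatures)
  k_detected <- integer(config$n_signatures)
  for (i in seq_along(signatures)) {
    res <- tryCatch(
      stratify(expr, survival_data, signatures[[i]],
               min_fraction = config$min_fraction, normalize = FALSE),
      error = function(e) {
        stop(sprintf("signature %d (seed %d) failed: %s",
                     i, config$master_seed + i, conditionMessage(e)),
             call. = FALSE)
      })
    k_detected[i] <- res$k
    pvalues[i] <- if (res$k >= 2L) res$logrank$pvalue else 1
  }
  summ <- summarize_benchmark(pvalues, original_p, config$alpha)
  structure(list(pvalues = pvalues, neglog10 = -log10(pvalues),
                 k_detected = k_detected,
                 n_single_cluster = sum(k_detected == 1L),
                 frac_significant = summ[["frac_significant"]],
                 frac_outperforming = summ[["frac_outperforming"]],
                 original_p = original_p, config = config),
            class = "benchmark_result")
}

#' Summarize benchmark p-values against the original signature
#'
#' `frac_significant` is the fraction of random signatures with p strictly
#' below `alpha`; `frac_outperforming` the fraction with p strictly below
#' the original signature's p (ties count for the original).
#'
#' @param pvalues numeric vector of per-signature log-rank p-values.
#' @param original_p the original signature's log-rank p (NA allowed).
#' @param alpha significance threshold.
#' @return Named numeric vector `frac_significant`, `frac_outperforming`.
#' @export
summarize_benchmark <- function(pvalues, original_p = NA_real_,
                                alpha = 0.05) {
  if (length(pvalues) == 0L) stop("empty p-value list")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  c(frac_significant = mean(pvalues < alpha),
    frac_outperforming = if (is.na(original_p)) NA_real_ else
      mean(pvalues < original_p))
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "benchmark_result: %d random signatures of size %d (master seed %d)\n",
    x$config$n_signatures, x$config$signature_size, x$config$master_seed))
  cat(sprintf("  significant at alpha = %g: %.1f%%\n",
              x$config$alpha, 100 * x$frac_significant))
  if (!is.na(x$original_p)) {
    cat(sprintf("  outperforming the original (p = %.3g): %.1f%%\n",
                x$original_p, 100 * x$frac_outperforming))
  }
  if (x$n_single_cluster > 0L) {
    cat(sprintf("  %d signature(s) yielded a single cluster (scored p = 1)\n",
                x$n_single_cluster))
  }
  invisible(x)
}
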