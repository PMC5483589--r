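#' Pipeline configuration
#'
#' Collects every input path and tunable threshold of the end-to-end
#' chain. Defaults follow the study design: FDR < 0.05 for significance,
#' minimum cluster fraction 0.125 for the whole cohort and 0.25 within a
#' subtype, alpha 0.05, and 1000 random benchmark signatures whose size
#' defaults to the mapped signature size.
#'
#' @param network_sif path to the SIF network file.
#' @param deg_paths character vector (>= 2) of DEG table TSVs.
#' @param gmt_path path to the gene-set GMT file.
#' @param expr_path path to the expression matrix TSV.
#' @param survival_path path to the survival annotation TSV.
#' @param probe_map_path optional probe-map TSV (probe-level matrices).
#' @param fdr_threshold DEG significance cutoff.
#' @param min_fraction whole-cohort minimum cluster fraction.
#' @param min_fraction_subtype per-subtype minimum cluster fraction.
#' @param alpha significance threshold.
#' @param benchmark_n number of random signatures.
#' @param benchmark_size random-signature size, or `"auto"` (mapped
#'   signature size).
#' @param master_seed integer master seed.
#' @param out_dir output directory for artifacts and the JSON report.
#' @param time_unit `"years"` or `"months"` for survival times.
#' @param row_kind `"gene"` or `"probe"` expression rows.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(network_sif, deg_paths, gmt_path, expr_path,
                            survival_path, probe_map_path = NULL,
                            fdr_threshold = 0.05, min_fraction = 0.125,
                            min_fraction_subtype = 0.25, alpha = 0.05,
                            benchmark_n = 1000L, benchmark_size = "auto",
                            master_seed = 1L, out_dir = "pipeline_out",
                            time_unit = c("years", "months"),
                            row_kind = c("gene", "probe")) {
  time_unit <- match.arg(time_unit)
  row_kind <- match.arg(row_kind)
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            min_fraction > 0, min_fraction <= 0.5,
            min_fraction_subtype > 0, min_fraction_subtype <= 0.5,
            alpha > 0, alpha < 1, benchmark_n >= 1L,
            length(deg_paths) >= 2L)
  structure(list(network_sif = network_sif, deg_paths = deg_paths,
                 gmt_path = gmt_path, expr_path = expr_path,
                 survival_path = survival_path,
                 probe_map_path = probe_map_path,
                 fdr_threshold = fdr_threshold, min_fraction = min_fraction,
                 min_fraction_subtype = min_fraction_subtype, alpha = alpha,
                 benchmark_n = as.integer(benchmark_n),
                 benchmark_size = benchmark_size,
                 master_seed = as.integer(master_seed), out_dir = out_dir,
                 time_unit = time_unit, row_kind = row_kind),
            class = "pipeline_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

#' Run the full integration and stratification pipeline
#'
#' Eagerly parses every input, then executes: stable-target intersection
#' across DEG tables, up/down split, gene-set over-representation
#' analysis, Steiner-tree module extraction, whole-cohort stratification
#' with log-rank testing, per-subtype stratification, and the
#' random-signature benchmark. All intermediate artifacts are written
#' under `config$out_dir` together with a deterministic `report.json`
#' (no timestamps in the report, so identical inputs and seed give
#' byte-identical output; progress logging goes to stderr).
#'
#' @param config a `pipeline_config`.
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # eager validation: parse every input before stage 1
  pipeline_log("validate", "parsing all inputs")
  net <- read_sif(config$network_sif)
  degs <- lapply(config$deg_paths, read_deg_table)
  collection <- read_gmt(config$gmt_path)
  expr <- read_expression_matrix(config$expr_path, row_kind = config$row_kind)
  surv <- read_survival_table(config$survival_path, unit = config$time_unit)
  probe_map <- if (!is.null(config$probe_map_path))
    read_probe_map(config$probe_map_path) else NULL
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  pipeline_log("targets", "intersecting %d DEG tables", length(degs))
  targets <- common_targets(degs, threshold = config$fdr_threshold)
  lists <- split_targets(targets)
  utils::write.table(targets, file.path(config$out_dir, "common_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pipeline_log("enrichment", "ORA of %d sets against all/up/down",
               length(collection))
  universe <- sort(Reduce(union, lapply(degs, function(d) d$gene)))
  enr <- enrich_all(lists, collection, universe, mode = "ora",
                    alpha = config$alpha)
  utils::write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pipeline_log("module", "Steiner module extraction")
  module <- build_module(net, targets, fdr_threshold = config$fdr_threshold)
  write_module(module, file.path(config$out_dir, "module"))

  signature <- names(module$annotation)
  pipeline_log("stratify", "whole cohort, %d-gene signature",
               length(signature))
  strat <- stratify(expr, surv, signature, probe_map = probe_map,
                    min_fraction = config$min_fraction)
  utils::write.table(
    data.frame(patient = names(strat$assignment),
               cluster = unname(strat$assignment)),
    file.path(config$out_dir, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  subtypes <- setdiff(unique(surv$subtype), "unknown")
  sub_res <- list()
  for (st in sort(subtypes)) {
    res <- tryCatch(
      stratify(expr, surv, signature, probe_map = probe_map,
               min_fraction = config$min_fraction_subtype,
               subtype_filter = st),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      pipeline_log("stratify", "subtype %s skipped: %s", st, res)
      sub_res[[st]] <- list(skipped = res)
    } else {
      sub_res[[st]] <- list(
        n_patients = res$n_patients, k = res$k,
        logrank_p = if (res$k >= 2L) res$logrank$pvalue else NULL,
        mfs5 = as.list(res$mfs5))
    }
  }

  gene_rows <- if (!is.null(probe_map))
    sort(unique(unname(probe_map))) else rownames(expr)
  pool <- build_gene_pool(collection, gene_rows)
  size <- if (identical(config$benchmark_size, "auto")) strat$n_mapped else
    as.integer(config$benchmark_size)
  size <- min(size, length(pool))
  bench_cfg <- benchmark_config(
    n_signatures = config$benchmark_n, signature_size = size,
    alpha = config$alpha, master_seed = config$master_seed,
    min_fraction = config$min_fraction)
  pipeline_log("benchmark", "%d random signatures of size %d",
               bench_cfg$n_signatures, bench_cfg$signature_size)
  original_p <- if (strat$k >= 2L) strat$logrank$pvalue else 1
  bench <- run_benchmark(expr, surv, pool, bench_cfg,
                         original_p = original_p, probe_map = probe_map)
  utils::write.table(
    data.frame(signature = seq_along(bench$pvalues),
               logrank_p = bench$pvalues, neglog10 = bench$neglog10,
               k = bench$k_detected),
    file.path(config$out_dir, "benchmark_pvalues.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    parameters = list(
      fdr_threshold = config$fdr_threshold,
      min_fraction = config$min_fraction,
      min_fraction_subtype = config$min_fraction_subtype,
      alpha = config$alpha, master_seed = config$master_seed,
      benchmark_n = bench_cfg$n_signatures,
      benchmark_size = bench_cfg$signature_size,
      time_unit = config$time_unit),
    inputs = list(
      network_nodes = length(net$nodes),
      network_edges = nrow(net$edges),
      deg_tables = length(degs),
      gene_sets = length(collection),
      patients = ncol(expr)),
    targets = list(
      n_common = nrow(targets), n_up = length(lists$up),
      n_down = length(lists$down),
      n_discordant = length(attr(targets, "discordant"))),
    enrichment = list(
      n_significant = sum(enr$significant, na.rm = TRUE),
      top_set = enr$set_name[which.min(enr$qvalue)]),
    module = list(
      terminals = unname(module$counts[["terminals"]]),
      steiner = unname(module$counts[["steiner"]]),
      total = unname(module$counts[["total"]]),
      unmapped_targets = length(module$unmapped)),
    stratification = list(
      n_patients = strat$n_patients, signature_mapped = strat$n_mapped,
      signature_unmapped = length(strat$unmapped), k = strat$k,
      logrank_chi_square = if (strat$k >= 2L) strat$logrank$chi_square else NULL,
      logrank_p = if (strat$k >= 2L) strat$logrank$pvalue else NULL,
      mfs5 = as.list(strat$mfs5)),
    subtype_stratification = sub_res,
    benchmark = list(
      pool_size = length(pool),
      frac_significant = bench$frac_significant,
      frac_outperforming = bench$frac_outperforming,
      n_single_cluster = bench$n_single_cluster))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("done", "report written to %s",
               file.path(config$out_dir, "report.json"))
  invisible(report)
}
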