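# Writes a complete synthetic input bundle (network SIF, three DEG TSVs,
# GMT, expression TSV, survival TSV) under `dir` and returns a
# pipeline_config for it. The cohort's planted prognosis groups express
# their pattern on the planted network-module genes, so the extracted
# module signature is genuinely prognostic in the fixture.
make_pipeline_fixture <- function(dir, seed = 1, n_patients = 80,
                                  benchmark_n = 25) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gn <- gen_network(n_nodes = 70, edge_prob = 0.03, module_size = 12,
                    seed = seed)
  write_sif(gn$network, file.path(dir, "network.sif"))
  degs <- gen_deg_tables(gn$network, gn$module_nodes, n_tables = 3,
                         frac_module_significant = 0.8, n_background = 4,
                         seed = seed)
  deg_paths <- file.path(dir, sprintf("deg%d.tsv", 1:3))
  for (i in 1:3) write_deg_table(degs[[i]], deg_paths[i])

  co <- gen_cohort(n_patients = n_patients, n_genes = 150,
                   signature_genes = gn$module_nodes,
                   expression_effect = 2, hazard_ratios = c(1, 3),
                   subtype_labels = c("LumA", "Basal"),
                   subtype_props = c(0.5, 0.5), seed = seed + 1)
  write_expression_matrix(co$expr, file.path(dir, "expr.tsv"),
                          id_column = "gene")
  utils::write.table(co$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  gmt <- gen_gmt(n_sets = 8, set_size_range = c(10, 40),
                 universe = rownames(co$expr),
                 planted_genes = attr(degs, "planted_significant"),
                 planted_overlap = 8, planted_size = 20, seed = seed)
  write_gmt(gmt, file.path(dir, "sets.gmt"))

  pipeline_config(
    network_sif = file.path(dir, "network.sif"),
    deg_paths = deg_paths,
    gmt_path = file.path(dir, "sets.gmt"),
    expr_path = file.path(dir, "expr.tsv"),
    survival_path = file.path(dir, "survival.tsv"),
    benchmark_n = benchmark_n, benchmark_size = 10,
    master_seed = seed, out_dir = file.path(dir, "out"))
}
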