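#!/usr/bin/env Rscript
# Generates the synthetic study inputs all later steps consume: a signed
# signaling network with a planted 12-gene module, three DEG tables whose
# stable (shared-significant) genes sit on that module, a gene-set
# collection with one planted enriched set, and a 200-patient cohort whose
# two prognosis groups (hazard ratio 3) express their pattern on the
# module genes. Everything is seeded, so re-running reproduces the files
# byte for byte.

library(modstrat)

seed <- 1
in_dir <- "results/inputs"
dir.create(in_dir, showWarnings = FALSE, recursive = TRUE)

gn <- gen_network(n_nodes = 70, edge_prob = 0.03, module_size = 12,
                  seed = seed)
write_sif(gn$network, file.path(in_dir, "network.sif"))
writeLines(gn$module_nodes, file.path(in_dir, "planted_module.txt"))
message(sprintf("network: %d nodes, %d edges; planted module: %d genes",
                length(gn$network$nodes), nrow(gn$network$edges),
                length(gn$module_nodes)))

degs <- gen_deg_tables(gn$network, gn$module_nodes, n_tables = 3,
                       frac_module_significant = 0.8, n_background = 4,
                       seed = seed)
for (i in seq_along(degs)) {
  write_deg_table(degs[[i]], file.path(in_dir, sprintf("deg%d.tsv", i)))
}
message(sprintf("DEG tables: 3 comparisons, %d shared planted significant genes",
                length(attr(degs, "planted_significant"))))

co <- gen_cohort(n_patients = 200, n_genes = 300,
                 signature_genes = gn$module_nodes,
                 expression_effect = 2, hazard_ratios = c(1, 3),
                 subtype_labels = c("LumA", "LumB", "Basal"),
                 subtype_props = c(0.45, 0.3, 0.25), seed = seed + 1)
write_expression_matrix(co$expr, file.path(in_dir, "expr.tsv"),
                        id_column = "gene")
write.table(co$survival, file.path(in_dir, "survival.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(patient = names(co$groups),
                       group = unname(co$groups)),
            file.path(in_dir, "planted_groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("cohort: %d patients, %d genes, event fraction %.2f",
                ncol(co$expr), nrow(co$expr), mean(co$survival$event)))

gmt <- gen_gmt(n_sets = 15, set_size_range = c(10, 40),
               universe = rownames(co$expr),
               planted_genes = attr(degs, "planted_significant"),
               planted_overlap = 8, planted_size = 20, seed = seed)
write_gmt(gmt, file.path(in_dir, "sets.gmt"))
message(sprintf("gene sets: %d (incl. planted set of 20 with overlap 8)",
                length(gmt)))
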