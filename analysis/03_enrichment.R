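#!/usr/bin/env Rscript
# Tests gene-set enrichment of the stable targets two ways: hypergeometric
# over-representation of the all/up/down lists, and Wilcoxon rank-sum
# enrichment of the full gene p-value profile of the first comparison.
# Finds the planted set at the top of both rankings.

library(modstrat)

in_dir <- "results/inputs"
out_dir <- "results/enrichment"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

degs <- lapply(file.path(in_dir, sprintf("deg%d.tsv", 1:3)), read_deg_table)
collection <- read_gmt(file.path(in_dir, "sets.gmt"))
targets <- common_targets(degs, threshold = 0.05)
lists <- split_targets(targets)
universe <- sort(Reduce(union, lapply(degs, function(d) d$gene)))

ora <- enrich_all(lists, collection, universe, mode = "ora")
write.table(ora, file.path(out_dir, "ora.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- ora[!is.na(ora$qvalue) & ora$significant, ]
message(sprintf("ORA: %d significant (set, list) cells at q < 0.05", nrow(sig)))
top <- ora[ora$list_name == "all", ]
top <- top[order(top$qvalue), ][1:3, c("set_name", "overlap_count", "qvalue")]
print(top, row.names = FALSE)

pmap <- setNames(degs[[1]]$pvalue, degs[[1]]$gene)
rank_res <- enrich_all(NULL, collection, mode = "rank", pvalues = pmap)
write.table(rank_res, file.path(out_dir, "rank.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
tested <- rank_res[rank_res$testable, ]
message(sprintf("rank-based: %d of %d sets testable; top set %s (q = %.3g)",
                nrow(tested), nrow(rank_res),
                tested$set_name[which.min(tested$qvalue)],
                min(tested$qvalue)))
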