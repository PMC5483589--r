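# modstrat

Integration of perturbation transcriptomics with signed signaling
networks, and survival calibration of the resulting gene signature.

Breast-cancer perturbation studies typically end with three artifacts: a
handful of differential-expression (DEG) tables from related
comparisons, a curated signaling-network model, and public patient
cohorts with expression and metastasis-free-survival (MFS) annotation.
modstrat provides the chain that connects them, for computational
biologists who want each step reproducible and testable:

1. **Stable targets** — genes significant at FDR < 0.05 in *every*
   comparison, with sign-consistent fold-changes.
2. **Gene-set enrichment** — one-sided hypergeometric
   over-representation of the all/up/down target lists, and Wilcoxon
   rank-sum enrichment of the full gene p-value profile, each with
   Benjamini–Hochberg adjustment across sets.
3. **Network module induction** — mapped targets become terminals
   *T* of a Steiner-tree search in the undirected network; the
   metric-closure heuristic (cost ≤ 2(1 − 1/|T|) × optimal, verified
   in-suite against an exact enumeration oracle) adds connector
   "Steiner" nodes, and the signed directed subnetwork induced on all
   tree nodes is the module.
4. **Survival stratification** — module genes form a signature;
   patients are clustered on Pearson-correlation distance
   d(i,j) = 1 − r(i,j) with complete linkage, clusters are detected by
   a dynamic hybrid dendrogram cut whose only parameter is the minimum
   cluster fraction (0.125 whole-cohort, 0.25 within a subtype), and
   cluster survival is compared by Kaplan–Meier estimation and the
   k-sample log-rank test.
5. **Random-signature benchmark** — the identical chain is re-run for
   equally sized random signatures drawn from a pathway-gene pool,
   reporting the fraction significant at α = 0.05 and the fraction with
   a strictly smaller log-rank p than the original signature.

Seeded generators (`gen_network()`, `gen_deg_tables()`, `gen_gmt()`,
`gen_cohort()`, `gen_probe_map()`) plant known structure — a connected
network module, shared significant targets, an enriched set, prognosis
groups with exponential hazards and independent censoring — so the
entire chain runs and is validated without any external data.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate_inputs.R` … `05_random_benchmark.R`); each script is a
thin driver over the package functions and writes its tables under
`results/`. Running them in order prints, among other things:

```
$ Rscript analysis/02_extract_module.R
stable targets significant in all 3 comparisons: 10 (4 up, 6 down)
steiner_module: 10 terminals + 0 Steiner nodes = 10 module nodes, 11 signed edges
planted module genes recovered as terminals: 10 / 10 significant

$ Rscript analysis/04_stratify_survival.R
stratification: 200 patients, 10 signature genes mapped, k = 2 cluster(s)
log-rank: chi-square = 50.78 on 1 df, p = 1.034e-12 (2 groups)
  5-year MFS per cluster: cluster1=0.681, cluster2=0.343
agreement with planted prognosis groups: ARI = 1.000

$ Rscript analysis/05_random_benchmark.R
benchmark_result: 200 random signatures of size 10 (master seed 1)
  significant at alpha = 0.05: 17.5%
  outperforming the original (p = 1.03e-12): 0.0%
```

Reading: the three simulated comparisons share 10 stable targets, all of
which lie on the planted network module and come back as Steiner-tree
terminals (this module needed no connector nodes; terminals + Steiner =
total is an invariant). Clustering the 200 simulated patients on those
genes recovers the two planted prognosis groups exactly (adjusted Rand
index 1.0); their 5-year MFS rates differ by ~0.34 and the log-rank test
is decisive. No random signature of equal size beats the planted one.

The same chain runs from files in one call:

```r
library(modstrat)
cfg <- pipeline_config(
  network_sif = "results/inputs/network.sif",
  deg_paths = sprintf("results/inputs/deg%d.tsv", 1:3),
  gmt_path = "results/inputs/sets.gmt",
  expr_path = "results/inputs/expr.tsv",
  survival_path = "results/inputs/survival.tsv",
  benchmark_n = 200, master_seed = 1, out_dir = "results/pipeline")
run_pipeline(cfg)   # deterministic report.json + all intermediate tables
```

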