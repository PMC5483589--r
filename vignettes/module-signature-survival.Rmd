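---
title: "From differential targets to a prognostic network-module signature"
author: "modstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From differential targets to a prognostic network-module signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis chain

modstrat implements a five-stage integration chain for perturbation
transcriptomics and patient survival data:

1. **Stable targets.** Genes significant (FDR < 0.05) in *every* one of
   several differential-expression comparisons form the stable target
   list; the consensus fold-change comes from the first comparison, and
   genes whose fold-change sign flips between comparisons are excluded
   with a warning — a "stable target" should respond in one direction.
2. **Enrichment.** Target lists (all / up / down by fold-change sign) are
   tested against a gene-set collection by the one-sided hypergeometric
   tail (over-representation), and the full gene p-value profile by a
   one-sided Wilcoxon rank-sum test; Benjamini–Hochberg adjustment is
   applied across sets within each list.
3. **Module induction.** Significant targets are mapped onto a signed
   directed signaling network; the mapped nodes become *terminals* of a
   Steiner-tree search in the undirected view; connector (*Steiner*)
   nodes are added only where needed; the signed directed subnetwork
   induced on all tree nodes is the module.
4. **Stratification.** Module genes act as an expression signature:
   patients are clustered by correlation distance with complete linkage,
   clusters are detected by a dynamic hybrid dendrogram cut, and
   metastasis-free survival (MFS) is compared across clusters with
   Kaplan–Meier estimation and a k-sample log-rank test.
5. **Random-signature benchmark.** The same stratification chain is run
   for many equally sized random signatures drawn from a pathway-gene
   pool, calibrating how unusual the original signature's log-rank
   p-value really is.

Every stage is exercised end to end on synthetic data with planted
structure, so the whole chain is testable without any external download.

## Steiner-tree module induction

The tree search uses the classic metric-closure (shortest-path)
heuristic: build the complete graph on the terminals weighted by
breadth-first distances, take its minimum spanning tree, expand each
closure edge into one concrete shortest path, take a spanning tree of
the union, and repeatedly prune non-terminal leaves. The resulting tree
costs at most $2(1 - 1/|T|)$ times the optimum for $|T|$ terminals; the
package ships an exhaustive-enumeration exact solver (feasible to 16
nodes) used by the test-suite to verify that bound on hundreds of random
instances.

Determinism was a design goal: every tie — in the closure MST, in
shortest-path expansion, in the final spanning tree — is broken by
lexicographic node order, so the same inputs yield the same module on
any platform. Edges are unweighted (the network model carries signs, not
strengths), signs are ignored during the search and re-attached in the
induced subnetwork, and fold-change annotations are clamped to ±2 only
in the display copy; raw values are retained. When terminals fall into
several network components the bare tree search refuses with the
component partition, while `build_module()` runs the search per
component and unions the forests, so no target is silently dropped.

## Enrichment conventions

The over-representation p-value is the upper hypergeometric tail
$P(X \ge k)$ for overlap $k$ between an $n$-gene list and a $K$-gene set
inside an $N$-gene universe. The universe is caller-supplied and
defaults to the union of all DEG-table genes — the measured-gene
universe, the conservative standard. The rank-based test is one-sided
toward smaller in-set p-values ("enrichment" is directional); it uses
the exact null distribution when both groups have ≤ 25 genes and no
ties, the tie-corrected normal approximation otherwise. Sets with no
scored gene inside (or none outside) are reported untestable rather
than given a fabricated p-value, and empty up/down lists likewise.

## Patient stratification

Preprocessing follows standard microarray practice: probe-level
matrices are collapsed per gene to the probe with the highest mean
expression (ties to the lexicographically smallest probe id), and
quantile normalization equalizes the per-patient distributions (ties
within a column receive the average of their target values, so exact
sorted-value identity across columns holds only for tie-free data).
Missing values are rejected at ingest rather than imputed — no
imputation rule is part of the model. Times are in years; a
`unit = "months"` flag divides by 12 on ingest. Five-year MFS is the
product-limit estimate $S(5)$.

Patient distance is $d(i,j) = 1 - r(i,j)$, the Pearson correlation of
the two signature-gene profiles, and clustering is complete linkage.
Cluster detection is a two-stage *dynamic hybrid cut* parameterized only
by a minimum cluster size, expressed as a fraction of the cohort
(default 0.125 whole-cohort, 0.25 within a molecular subtype), with the
floor `max(2, floor(fraction * n))` — the conservative rounding of a
fractional specification.

Stage 1 reads the number of clusters off the dendrogram shape. With
merge heights sorted decreasingly $H_1 \ge H_2 \ge \dots$, between-cluster
merges occupy the top of that sequence and within-cluster merges the
rest; the widest gap $H_t - H_{t+1}$ within the admissible top region
(at most $n/\text{floor}$ merges can separate floor-sized clusters)
marks the boundary, and the tree is cut just below $H_t$, giving $t+1$
branches. A fixed height quantile was considered and rejected: any
fixed quantile of the $n-1$ merge heights lands below the second and
third largest height once $n$ is in the hundreds, so it always severs
the top two or three merges whether or not the data support that many
clusters, and it splits one genuine group in two. The widest-gap rule is
scale-free, adapts to the actual shape, and degrades gracefully: when
the considered heights are all equal (equidistant patients) there is no
gap and everything stays in one cluster. Stage 2 assigns every patient
in a branch below the size floor to the seed cluster with the smallest
mean dissimilarity. Both stages are deterministic; gap ties resolve to
the highest cut (fewest clusters).

Survival comparison is the unweighted k-sample log-rank test (one
global test across all detected clusters, $k-1$ degrees of freedom, no
continuity correction) on the full follow-up; the 15-year horizon
stored on KM curves affects plotting only. Subjects censored exactly at
an event time remain in that risk set — the standard product-limit
convention, stated here because it is load-bearing for reproducing any
published chi-square.

## Random-signature benchmark

The pool is the deduplicated union of all collection gene sets
restricted to genes measured on the array. Each of the `n_signatures`
draws (study default 1000, size default 76) is a uniform sample without
replacement; draw $i$ uses seed `master_seed + i`, so the whole
benchmark is reproducible and any single draw can be replayed in
isolation. Signatures for which the cut detects a single cluster have
no testable survival contrast; they score $p = 1$ and are counted,
because dropping them would bias the significant fraction upward.
"Outperforming" means a *strictly* smaller log-rank p-value than the
original signature — ties count in the original's favor.

## What the generators emulate — and what they do not

`gen_network()` plants a connected module inside a random directed
signed graph and bridges it to the largest remaining component;
`gen_deg_tables()` marks a seeded subset of module genes significant in
every comparison with sign-consistent fold-changes, plus table-specific
background; `gen_gmt()` can plant a set with a stated overlap with a
target list; `gen_probe_map()` expands genes into probes with a known
best probe. `gen_cohort()` assigns patients equiprobably to prognosis
groups, gives survival times an exponential hazard
`baseline_hazard * hazard_ratio[group]` (defaults 0.08/year and ratios
(1, 3), a realistic metastasis-rate contrast) under independent
exponential censoring (0.04/year) plus administrative censoring at 20
years, and draws subtype labels independently of the prognosis groups
so that signature clusters and subtype clusters can be told apart.

One modeling choice deserves emphasis: the between-group expression
difference is planted as a per-gene random ±`expression_effect` *pattern*
(in SD units of the unit-variance noise), not as a constant shift.
Pearson correlation is location-invariant, so a constant shift across
all signature genes would be invisible to the clustering chain; a
pattern is both detectable and the realistic way co-regulated modules
differ between patient groups.

The generators deliberately do *not* mimic microarray batch effects,
RNA-Seq count distributions, probe saturation, or any real pathway
topology. Tests passing on this synthetic structure demonstrate that
the chain's logic and statistics are correct under its stated
assumptions — not that the biological conclusions of any particular
cohort transfer.

## Numerical choices and problem sizes

* All gene symbols are uppercased at every ingest point so network,
  DEG, gene-set and expression identifiers match exactly.
* Duplicate identical network edges are deduplicated; the same ordered
  pair with conflicting signs is an error (silent overwrite would hide
  curation mistakes). Self-loops are rejected unless explicitly allowed.
* BH adjustment, the hypergeometric tail, Wilcoxon, complete-linkage
  clustering, Kaplan–Meier and the log-rank statistic are delegated to
  `stats`, `limma` and `survival`; the test-suite checks each against an
  independent oracle (literal enumeration, step-up definition, naive
  agglomeration, hand risk-table tabulation).
* The test-suite and the acceptance script run at desk scale: networks
  of 60–120 nodes with 10–12-gene planted modules, cohorts of 100–200
  patients with 200–300 genes, 200 benchmark signatures, and 1000-fold
  calibration loops — sizes at which every statistical property checked
  (approximation bounds, null calibration within binomial tolerance,
  planted-structure recovery) is already sharply testable.

## Known limitations

* The dynamic cut recovers cluster numbers only as well as the
  dendrogram separates them; overlapping groups at small effect sizes
  will merge, and the widest-gap rule reads exactly one cut level — it
  will not find nested sub-clusters below the first boundary within the
  same run (subtype-restricted reruns serve that purpose).
* The exact Steiner solver is an oracle, not a tool: it enumerates node
  subsets and is limited to 16-node graphs.
* The metric-closure heuristic guarantees the 2-approximation but not
  equivalence with any other Steiner implementation's node choice, so
  connector-node identities may differ between tools even at equal cost.
* Benchmark p-values inherit the discreteness of log-rank on small
  groups; on small cohorts the null distribution is only approximately
  uniform.
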