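make_deg <- function(genes, fdr, fc = 1, label = "cmp") {
  deg_table(data.frame(gene = genes, log2fc = fc, pvalue = fdr / 2,
                       fdr = fdr), label)
}

test_that("stable targets are the intersection of significant sets", {
  t1 <- make_deg(c("A", "B", "C", "X"), c(0.01, 0.02, 0.03, 0.5))
  t2 <- make_deg(c("B", "C", "D"), c(0.01, 0.01, 0.01))
  t3 <- make_deg(c("C", "B"), c(0.04, 0.04))
  ct <- common_targets(list(t1, t2, t3))
  expect_equal(ct$gene, c("B", "C"))
  # consensus fold-change from the first table
  expect_equal(ct$log2fc, c(1, 1))

  # identical one-gene tables give that gene
  one <- make_deg("G1", 0.01)
  expect_equal(common_targets(list(one, one, one))$gene, "G1")

  # a table without significant genes empties the intersection
  none <- make_deg(c("A", "B"), c(0.9, 0.8))
  expect_equal(nrow(common_targets(list(t1, none))), 0L)

  expect_error(common_targets(list(t1)), "two")
})

test_that("discordant fold-change signs are excluded with a warning", {
  t1 <- make_deg(c("A", "B"), c(0.01, 0.01), fc = c(1, 1))
  t2 <- make_deg(c("A", "B"), c(0.01, 0.01), fc = c(1, -1))
  expect_warning(ct <- common_targets(list(t1, t2)), "discordant")
  expect_equal(ct$gene, "A")
  expect_equal(attr(ct, "discordant"), "B")
})

test_that("up/down split follows the fold-change sign with 0 in all only", {
  lists <- split_targets(data.frame(gene = c("A", "B", "C", "D"),
                                    log2fc = c(1, -1, 2, 0)))
  expect_equal(lists$up, c("A", "C"))
  expect_equal(lists$down, "B")
  expect_equal(lists$all, c("A", "B", "C", "D"))

  allpos <- split_targets(data.frame(gene = c("A", "B"), log2fc = c(1, 2)))
  expect_length(allpos$down, 0L)
})

test_that("ORA matches literal enumeration on the worked example", {
  universe <- sprintf("U%02d", 1:20)
  gset <- universe[1:6]
  glist <- c(universe[1:4], universe[10])  # overlap 4
  res <- fisher_ora(glist, gset, universe)
  expect_equal(res$overlap_count, 4L)
  manual <- (choose(6, 4) * choose(14, 1) + choose(6, 5) * choose(14, 0)) /
    choose(20, 5)
  expect_equal(res$pvalue, manual, tolerance = 1e-12)
  expect_equal(res$pvalue, oracle_hyper_enum(universe, gset, 5, 4),
               tolerance = 1e-12)

  # set covering the universe forces p = 1
  expect_equal(fisher_ora(glist, universe, universe)$pvalue, 1)
  # minimum possible overlap gives the full tail
  expect_equal(fisher_ora(universe[7:9], gset, universe)$pvalue,
               oracle_hyper_tail(20, 6, 3, 0), tolerance = 1e-12)

  expect_error(fisher_ora(character(), gset, universe), "empty")
  expect_error(fisher_ora(glist, gset, character()), "empty")
})

test_that("ORA equals the combinatorial tail across small configurations", {
  for (seed in 1:40) {
    set.seed(seed)
    N <- sample(5:30, 1)
    universe <- sprintf("U%02d", 1:N)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    gset <- sample(universe, K)
    glist <- sample(universe, n)
    res <- fisher_ora(glist, gset, universe)
    expect_equal(res$pvalue,
                 oracle_hyper_tail(N, K, n, res$overlap_count),
                 tolerance = 1e-12)
    # permutation invariance of all inputs
    res2 <- fisher_ora(sample(glist), sample(gset), sample(universe))
    expect_equal(res$pvalue, res2$pvalue)
  }
})

test_that("rank enrichment is exact on the extreme ordering", {
  p <- setNames(c(0.01, 0.02, 0.03, 0.4, 0.5, 0.6), sprintf("G%d", 1:6))
  # set = the 3 smallest p-values: most extreme of the C(6,3) assignments
  expect_equal(wilcoxon_rank_enrichment(p, c("G1", "G2", "G3")),
               1 / choose(6, 3), tolerance = 1e-12)
  # symmetric placement (in-set ranks 1, 4, 5 sit at the null median)
  p2 <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), sprintf("G%d", 1:6))
  expect_equal(wilcoxon_rank_enrichment(p2, c("G1", "G4", "G5")), 0.5,
               tolerance = 1e-12)
  expect_error(wilcoxon_rank_enrichment(p, sprintf("G%d", 1:6)), "outside")
})

test_that("rank enrichment is calibrated under the null", {
  set.seed(7)
  rejected <- 0L
  n_sim <- 1000L
  for (i in seq_len(n_sim)) {
    p <- setNames(runif(40), sprintf("G%02d", 1:40))
    members <- sample(names(p), 10)
    if (wilcoxon_rank_enrichment(p, members) < 0.05) rejected <- rejected + 1L
  }
  expect_gte(rejected / n_sim, 0.03)
  expect_lte(rejected / n_sim, 0.07)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  for (seed in 1:50) {
    set.seed(seed)
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("collection-wide enrichment flags the planted set first", {
  set.seed(211)  # distinct from the collection seed so random sets are
  universe <- sprintf("U%03d", 1:200)  # independent of the target draw
  targets <- data.frame(gene = sample(universe, 30),
                        log2fc = rnorm(30, 1, 0.2))
  gmt <- gen_gmt(n_sets = 15, set_size_range = c(10, 25),
                 universe = universe, planted_genes = targets$gene,
                 planted_overlap = 15, planted_size = 20, seed = 11)
  lists <- split_targets(targets)
  res <- enrich_all(lists, gmt, universe, mode = "ora")
  all_rows <- res[res$list_name == "all", ]
  expect_equal(all_rows$set_name[which.min(all_rows$qvalue)], "PLANTED")
  expect_true(all(res$qvalue >= res$pvalue - 1e-15, na.rm = TRUE))
  expect_true(all(res$pvalue >= 0 & res$pvalue <= 1, na.rm = TRUE))

  # a fold-change-free down list is reported untestable, not p = 0
  up_only <- split_targets(data.frame(gene = targets$gene, log2fc = 1))
  res2 <- enrich_all(up_only, gmt, universe, mode = "ora")
  expect_true(all(!res2$testable[res2$list_name == "down"]))
  expect_true(all(is.na(res2$pvalue[res2$list_name == "down"])))
})

test_that("rank-mode enrichment ranks the planted set first", {
  set.seed(12)
  universe <- sprintf("U%03d", 1:150)
  p <- setNames(runif(150), universe)
  gmt <- gen_gmt(n_sets = 10, set_size_range = c(10, 20),
                 universe = universe, seed = 12)
  planted <- names(sort(p))[1:12]
  gmt[["PLANTED"]] <- planted
  res <- enrich_all(NULL, gmt, mode = "rank", pvalues = p)
  expect_equal(res$set_name[which.min(res$qvalue)], "PLANTED")
})

test_that("under a global null few sets reach q < 0.05", {
  set.seed(31)
  universe <- sprintf("U%03d", 1:300)
  n_sig_cells <- 0L
  n_cells <- 0L
  for (i in 1:100) {
    targets <- data.frame(gene = sample(universe, 25),
                          log2fc = rnorm(25))
    gmt <- gen_gmt(n_sets = 5, set_size_range = c(10, 30),
                   universe = universe, seed = 1000 + i)
    res <- enrich_all(split_targets(targets), gmt, universe, mode = "ora")
    n_sig_cells <- n_sig_cells + sum(res$significant, na.rm = TRUE)
    n_cells <- n_cells + sum(res$testable)
  }
  expect_lte(n_sig_cells / n_cells, 0.05)
})

test_that("GMT round trip preserves the collection", {
  universe <- sprintf("U%02d", 1:40)
  gmt <- gen_gmt(n_sets = 6, set_size_range = c(5, 10), universe = universe,
                 seed = 4)
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gmt, f)
  back <- read_gmt(f)
  expect_equal(names(back), names(gmt))
  for (nm in names(gmt)) {
    expect_equal(as.character(back[[nm]]), as.character(gmt[[nm]]))
  }
  writeLines("ONLYNAME\tdesc", f)
  expect_error(read_gmt(f), "malformed")
})

test_that("DEG table I/O validates and round-trips", {
  d <- deg_table(data.frame(gene = c("a", "B"), log2fc = c(1, -1),
                            pvalue = c(0.001, 0.5), fdr = c(0.01, 0.6)))
  expect_equal(d$gene, c("A", "B"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_deg_table(d, f)
  back <- read_deg_table(f)
  expect_equal(back$gene, d$gene)
  expect_equal(back$fdr, d$fdr)
  expect_error(deg_table(data.frame(gene = c("A", "A"), log2fc = 1,
                                    pvalue = 0.1, fdr = 0.1)),
               "duplicate")
})
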