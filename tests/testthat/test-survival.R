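sim_cohort_small <- function(seed = 1, n = 60, effect = 2,
                             hr = c(1, 3), sig = sprintf("SIG%04d", 1:15)) {
  gen_cohort(n_patients = n, n_genes = 80, signature_genes = sig,
             expression_effect = effect, hazard_ratios = hr, seed = seed)
}

test_that("probe collapse keeps the probe with the highest mean", {
  expr <- expression_matrix(
    matrix(c(5, 5, 7, 7, 1, 2), nrow = 3, byrow = TRUE,
           dimnames = list(c("P1", "P2", "P3"), c("S1", "S2"))),
    row_kind = "probe")
  map <- c(P1 = "G1", P2 = "G1", P3 = "G2")
  out <- collapse_probes(expr, map)
  expect_equal(unname(out["G1", ]), c(7, 7))   # P2 has mean 7 > 5
  expect_equal(attr(out, "chosen_probe")[["G1"]], "P2")

  # tie goes to the lexicographically smallest probe id
  tie <- expression_matrix(
    matrix(c(3, 5, 5, 3), nrow = 2, byrow = TRUE,
           dimnames = list(c("PB", "PA"), c("S1", "S2"))),
    row_kind = "probe")
  out2 <- collapse_probes(tie, c(PA = "G1", PB = "G1"))
  expect_equal(attr(out2, "chosen_probe")[["G1"]], "PA")

  # one probe per gene is the identity up to renaming
  single <- expression_matrix(
    matrix(1:4, nrow = 2, dimnames = list(c("P1", "P2"), c("S1", "S2"))),
    row_kind = "probe")
  out3 <- collapse_probes(single, c(P1 = "GA", P2 = "GB"))
  expect_equal(unname(out3["GA", ]), unname(single["P1", ]))

  expect_error(collapse_probes(single, c(ZZ = "GA")), "no probe")
})

test_that("generated probe expansions are recovered exactly", {
  co <- sim_cohort_small(seed = 9, n = 20)
  pm <- gen_probe_map(co$expr, probes_per_gene_range = c(1, 3),
                      noise_sd = 0.05, seed = 9)
  out <- collapse_probes(pm$probe_expr, pm$map)
  expect_setequal(rownames(out), rownames(co$expr))
  # the planted top-offset probe wins for every gene
  chosen <- attr(out, "chosen_probe")
  expect_equal(chosen[names(pm$top_probe)], pm$top_probe)
  # 1-probe-per-gene expansion with zero noise is an exact round trip
  pm1 <- gen_probe_map(co$expr, probes_per_gene_range = c(1, 1),
                       noise_sd = 0, seed = 9)
  out1 <- collapse_probes(pm1$probe_expr, pm1$map)
  ord <- sort(rownames(co$expr))
  expect_equal(unname(out1[ord, ]), unname(co$expr[ord, ] + 1),
               tolerance = 1e-12)
})

test_that("quantile normalization equalizes sorted column values", {
  m <- expression_matrix(
    matrix(c(1, 3, 2, 4), nrow = 2,
           dimnames = list(c("G1", "G2"), c("S1", "S2"))))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "S1"]), c(1.5, 3.5))
  expect_equal(unname(out[, "S2"]), c(1.5, 3.5))

  # identical columns are a fixed point
  m2 <- expression_matrix(
    matrix(c(1, 5, 2, 1, 5, 2), nrow = 3,
           dimnames = list(c("G1", "G2", "G3"), c("S1", "S2"))))
  expect_equal(unname(quantile_normalize(m2)), unname(m2))

  # tie-free random matrices: sorted values identical across columns,
  # within-column rank order preserved
  set.seed(20)
  r <- expression_matrix(
    matrix(rnorm(200), nrow = 20,
           dimnames = list(sprintf("G%02d", 1:20), sprintf("S%02d", 1:10))))
  qn <- quantile_normalize(r)
  ref <- sort(qn[, 1])
  for (j in 2:ncol(qn)) {
    expect_equal(unname(sort(qn[, j])), unname(ref), tolerance = 1e-12)
    expect_equal(order(qn[, j]), order(r[, j]))
  }
  expect_warning(quantile_normalize(r[, 1, drop = FALSE]), "single")
})

test_that("signature subsetting reports mapped and unmapped genes", {
  co <- sim_cohort_small(seed = 2, n = 10)
  sig <- c(co$signature_genes[1:10], sprintf("MISS%02d", 1:3))
  sm <- signature_matrix(co$expr, sig)
  expect_equal(nrow(sm), 10L)
  expect_equal(attr(sm, "n_mapped"), 10L)
  expect_equal(attr(sm, "unmapped"), sort(sprintf("MISS%02d", 1:3)))
  expect_error(signature_matrix(co$expr, c("NO1", "NO2")), "fewer than 2")
})

test_that("correlation distance follows the textbook formula", {
  # affine transformation of a profile has distance 0; negation distance 2
  base <- matrix(c(1, 2, 3, 4, 2.5, 4.5, 6.5, 8.5, 4, 3, 2, 1),
                 nrow = 4,
                 dimnames = list(sprintf("G%d", 1:4), c("A", "B", "C")))
  d <- pearson_distance(base)
  expect_equal(d["A", "B"], 0, tolerance = 1e-12)
  expect_equal(d["A", "C"], 2, tolerance = 1e-12)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))

  set.seed(14)
  m <- matrix(rnorm(20), nrow = 5,
              dimnames = list(sprintf("G%d", 1:5), sprintf("S%d", 1:4)))
  d2 <- pearson_distance(m)
  for (i in 1:4) for (j in 1:4) {
    x <- m[, i]; y <- m[, j]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    manual <- 1 - r
    if (i == j) manual <- 0
    expect_equal(d2[i, j], manual, tolerance = 1e-12)
  }

  flat <- matrix(c(1, 1, 1, 1, 2, 3), nrow = 3,
                 dimnames = list(sprintf("G%d", 1:3), c("PFLAT", "POK")))
  expect_error(pearson_distance(flat), "PFLAT")
})

test_that("complete linkage matches a naive agglomeration oracle", {
  # forced order on a 3-point configuration
  d3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), nrow = 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- hclust_complete(d3)
  expect_equal(h$height, c(1, 10))

  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(n * 3), nrow = n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(sprintf("P%d", 1:n), sprintf("P%d", 1:n))
    h <- hclust_complete(d)
    expect_equal(h$height, oracle_complete_linkage_heights(d),
                 tolerance = 1e-10)
    expect_true(all(diff(h$height) >= -1e-12))
  }

  asym <- matrix(c(0, 1, 2, 0), nrow = 2)
  expect_error(hclust_complete(asym), "symmetric")
})

test_that("dynamic hybrid cut recovers planted groups and honors the floor", {
  pl <- planted_two_group_dist(20, seed = 5)
  h <- hclust_complete(pl$dist)
  cl <- dynamic_hybrid_cut(h, pl$dist, min_fraction = 0.25)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(mclust::adjustedRandIndex(cl, pl$labels), 1)

  # determinism
  expect_identical(cl, dynamic_hybrid_cut(h, pl$dist, min_fraction = 0.25))

  # equidistant points carry no shape information
  flat <- matrix(1, 10, 10); diag(flat) <- 0
  dimnames(flat) <- list(sprintf("P%d", 1:10), sprintf("P%d", 1:10))
  hf <- hclust_complete(flat)
  expect_equal(length(unique(dynamic_hybrid_cut(hf, flat, 0.2))), 1L)

  # too few observations for two floor-sized clusters
  small <- pl$dist[1:6, 1:6]
  hs <- hclust_complete(small)
  expect_equal(length(unique(dynamic_hybrid_cut(hs, small, 0.5))), 1L)

  expect_error(dynamic_hybrid_cut(h, pl$dist, 0.7), "min_fraction")
})

test_that("cut clusters never fall below the size floor", {
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(20:60, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 5), nrow = n)))
    dimnames(d) <- list(sprintf("P%02d", 1:n), sprintf("P%02d", 1:n))
    frac <- sample(c(0.125, 0.2, 0.25), 1)
    cl <- dynamic_hybrid_cut(hclust_complete(d), d, frac)
    floor_size <- max(2, floor(frac * n))
    expect_true(all(table(cl) >= floor_size))
    expect_equal(sort(unique(cl)), seq_along(unique(cl)))
  }
})

test_that("Kaplan-Meier estimates match the hand product-limit", {
  # (1, 2+, 3): S(1) = 2/3, S(3) = 0
  rec <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  km <- km_curve(rec)
  expect_equal(km_survival_at(km, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(km_survival_at(km, 2.5), 2 / 3, tolerance = 1e-12)
  expect_equal(km_survival_at(km, 3), 0, tolerance = 1e-12)
  expect_equal(km_survival_at(km, 0), 1)
  expect_equal(km_survival_at(km, 0.99), 1)

  # no events: flat at 1
  flat <- km_curve(data.frame(time = c(1, 2, 3), event = c(0, 0, 0)))
  expect_true(all(flat$surv == 1))

  # all events at once
  allev <- km_curve(data.frame(time = rep(1, 4), event = rep(1, 4)))
  expect_equal(km_survival_at(allev, 1), 0)

  expect_error(km_curve(data.frame(time = -1, event = 1)), "negative")
})

test_that("survival curves are monotone in [0, 1] on random inputs", {
  for (seed in 1:200) {
    set.seed(seed)
    n <- sample(3:40, 1)
    rec <- data.frame(time = rexp(n, 0.2),
                      event = rbinom(n, 1, 0.7))
    km <- km_curve(rec)
    expect_equal(km_survival_at(km, 0), 1)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
  }
})

test_that("log-rank matches the O-E/V tabulation and handles degeneracy", {
  # 4-subject worked example: group 1 events at 1, 2; group 2 at 3, 4
  rec <- data.frame(time = 1:4, event = 1)
  g <- c(1, 1, 2, 2)
  lr <- logrank_test(rec, g)
  expect_equal(lr$chi_square,
               oracle_logrank_chisq(rec$time, rec$event, g),
               tolerance = 1e-10)
  expect_equal(lr$df, 1L)

  # identical groups: chi-square 0, p = 1
  rec2 <- data.frame(time = rep(c(1, 2, 3), 2), event = rep(c(1, 0, 1), 2))
  lr2 <- logrank_test(rec2, rep(1:2, each = 3))
  expect_equal(lr2$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr2$pvalue, 1)

  # group-label permutation leaves the statistic unchanged
  set.seed(3)
  rec3 <- data.frame(time = rexp(30, 0.2), event = rbinom(30, 1, 0.8))
  g3 <- sample(1:3, 30, replace = TRUE)
  lr3 <- logrank_test(rec3, g3)
  relabeled <- c(2, 3, 1)[g3]
  expect_equal(logrank_test(rec3, relabeled)$chi_square, lr3$chi_square,
               tolerance = 1e-10)
  expect_equal(lr3$chi_square,
               oracle_logrank_chisq(rec3$time, rec3$event, g3),
               tolerance = 1e-8)

  # a subject censored before the first event never enters a risk set
  first_ev <- min(rec3$time[rec3$event == 1])
  rec4 <- rbind(rec3, data.frame(time = first_ev / 2, event = 0))
  g4 <- c(g3, 1)
  expect_equal(logrank_test(rec4, g4)$chi_square, lr3$chi_square,
               tolerance = 1e-10)

  expect_error(logrank_test(rec, rep(1, 4)), "2 groups")
  norec <- data.frame(time = 1:4, event = 0)
  expect_error(logrank_test(norec, g), "events")
})

test_that("log-rank null rejection rate is calibrated", {
  set.seed(13)
  n_sim <- 1000L
  rej <- 0L
  for (i in seq_len(n_sim)) {
    time <- rexp(100, 0.1)
    event <- as.integer(time < rexp(100, 0.05))
    time <- pmin(time, 20)
    g <- sample(1:2, 100, replace = TRUE)
    if (sum(event) == 0 || length(unique(g)) < 2) next
    p <- logrank_test(data.frame(time = time, event = event), g)$pvalue
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_sim, 0.035)
  expect_lte(rej / n_sim, 0.065)
})

test_that("the stratify chain recovers planted prognosis groups", {
  co <- gen_cohort(n_patients = 200, n_genes = 300,
                   signature_genes = sprintf("SIG%04d", 1:20),
                   expression_effect = 2, hazard_ratios = c(1, 3),
                   seed = 21)
  st <- stratify(co$expr, co$survival, co$signature_genes)
  expect_gte(st$k, 2L)
  expect_lt(st$logrank$pvalue, 0.01)
  ari <- mclust::adjustedRandIndex(st$assignment,
                                   co$groups[names(st$assignment)])
  expect_gt(ari, 0.9)
  expect_true(all(st$mfs5 >= 0 & st$mfs5 <= 1))

  # determinism of the full chain
  st2 <- stratify(co$expr, co$survival, co$signature_genes)
  expect_identical(st$assignment, st2$assignment)
  expect_identical(st$logrank$chi_square, st2$logrank$chi_square)

  expect_error(stratify(co$expr, co$survival, co$signature_genes,
                        subtype_filter = "Basal"),
               "subtype")
})

test_that("subtype filtering restricts the cohort and switches the floor", {
  co <- gen_cohort(n_patients = 160, n_genes = 200,
                   signature_genes = sprintf("SIG%04d", 1:15),
                   expression_effect = 2, hazard_ratios = c(1, 3),
                   subtype_labels = c("LumA", "Basal"),
                   subtype_props = c(0.6, 0.4), seed = 33)
  st <- stratify(co$expr, co$survival, co$signature_genes,
                 subtype_filter = "LumA")
  luma <- co$survival$patient[co$survival$subtype == "LumA"]
  expect_setequal(names(st$assignment), luma)
  expect_equal(st$min_fraction, 0.25)
  expect_true(all(rownames(st$subtype_composition) %in%
                    as.character(1:st$k)))
})

test_that("probe-level cohorts run through the full chain", {
  co <- sim_cohort_small(seed = 44, n = 80)
  pm <- gen_probe_map(co$expr, probes_per_gene_range = c(1, 2),
                      noise_sd = 0.05, seed = 44)
  st <- stratify(pm$probe_expr, co$survival, co$signature_genes,
                 probe_map = pm$map)
  expect_equal(st$n_patients, 80L)
  expect_gte(st$k, 1L)
})

test_that("survival table I/O converts months and validates events", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient\ttime\tevent\tsubtype",
               "P1\t24\t1\tLumA", "P2\t60\t0\tBasal"), f)
  d <- read_survival_table(f, unit = "months")
  expect_equal(d$time, c(2, 5))
  writeLines(c("patient\ttime\tevent", "P1\t1\t2"), f)
  expect_error(read_survival_table(f), "event")
})
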