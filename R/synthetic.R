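#' Generate a signed signaling network with a planted connected module
#'
#' Erdos-Renyi-style directed graph with random activation/inhibition
#' signs. A designated subset of `module_size` nodes is wired to be
#' connected in the undirected view (a random spanning tree over the
#' module is added), and one bridge edge links the module to the largest
#' component of the remaining graph, so that downstream Steiner extraction
#' has a recoverable target. Deterministic per seed.
#'
#' @param n_nodes number of genes (nodes).
#' @param edge_prob probability of each ordered node pair carrying an edge.
#' @param module_size planted module size (<= n_nodes).
#' @param inhibition_fraction fraction of edges that are inhibitions.
#' @param seed integer seed.
#' @return List: `network` (a `signaling_network`) and `module_nodes`
#'   (sorted character vector of planted module genes).
#' @export
gen_network <- function(n_nodes = 120L, edge_prob = 0.02, module_size = 10L,
                        inhibition_fraction = 0.3, seed = 1L) {
  stopifnot(n_nodes >= 1L, module_size >= 1L, module_size <= n_nodes,
            edge_prob >= 0, edge_prob <= 1,
            inhibition_fraction >= 0, inhibition_fraction <= 1)
  set.seed(seed)
  nodes <- sprintf("G%04d", seq_len(n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  hit <- stats::runif(nrow(pairs)) < edge_prob
  edges <- pairs[hit, , drop = FALSE]
  module <- sort(sample(nodes, module_size))
  if (module_size > 1L) {
    perm <- sample(module)
    tree <- lapply(2:module_size, function(i) {
      anchor <- perm[sample.int(i - 1L, 1L)]
      if (stats::runif(1) < 0.5) c(anchor, perm[i]) else c(perm[i], anchor)
    })
    tree <- do.call(rbind, tree)
    edges <- rbind(edges,
                   data.frame(source = tree[, 1], target = tree[, 2],
                              stringsAsFactors = FALSE))
  }
  rest <- setdiff(nodes, module)
  if (length(rest) > 0L) {
    # bridge the module to the largest component of the non-module graph
    rest_edges <- edges[edges$source %in% rest & edges$target %in% rest, ]
    g_rest <- igraph::graph_from_data_frame(rest_edges, directed = FALSE,
                                            vertices = data.frame(name = rest))
    comp <- igraph::components(g_rest)
    big <- names(comp$membership)[comp$membership == which.max(comp$csize)]
    edges <- rbind(edges, data.frame(source = sample(module, 1L),
                                     target = sample(big, 1L),
                                     stringsAsFactors = FALSE))
  }
  key <- paste(edges$source, edges$target)
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges$sign <- ifelse(stats::runif(nrow(edges)) < inhibition_fraction,
                       "inhibition", "activation")
  net <- signaling_network(edges, nodes = nodes,
                           name = sprintf("synthetic-net-seed%d", seed))
  list(network = net, module_nodes = module)
}

#' Generate differential-expression tables with a planted module signal
#'
#' Each table marks the same seeded subset of the planted module genes as
#' significant (FDR drawn below 0.05, fold-change signs consistent across
#' tables) plus table-specific background significant genes and
#' non-significant fillers. The intersection of significant sets across
#' tables therefore recovers the planted significant module subset, up to
#' background genes that happen to collide (reported in the `collisions`
#' attribute).
#'
#' @param network a `signaling_network` (supplies the gene universe).
#' @param planted_module character vector of planted module genes.
#' @param n_tables number of comparisons (study design: 3).
#' @param frac_module_significant fraction of module genes significant in
#'   every table.
#' @param n_background table-specific significant background genes.
#' @param n_filler non-significant filler genes per table.
#' @param seed integer seed.
#' @return List of `deg_table` objects with attributes `planted_significant`
#'   (the shared significant module subset) and `collisions` (background
#'   genes significant in every table).
#' @export
gen_deg_tables <- function(network, planted_module, n_tables = 3L,
                           frac_module_significant = 1, n_background = 0L,
                           n_filler = 40L, seed = 1L) {
  stopifnot(inherits(network, "signaling_network"),
            frac_module_significant >= 0, frac_module_significant <= 1,
            n_tables >= 1L)
  set.seed(seed)
  planted_module <- sort(unique(canonical_symbol(planted_module)))
  n_sig <- round(frac_module_significant * length(planted_module))
  sig_module <- if (n_sig > 0L) sort(sample(planted_module, n_sig)) else
    character()
  sign_of <- stats::setNames(sample(c(-1, 1), length(sig_module),
                                    replace = TRUE), sig_module)
  non_module <- setdiff(network$nodes, planted_module)
  extra <- sprintf("EXT%04d", seq_len(n_filler))
  tables <- vector("list", n_tables)
  bg_sets <- vector("list", n_tables)
  for (t in seq_len(n_tables)) {
    bg <- if (n_background > 0L)
      sort(sample(non_module, min(n_background, length(non_module)))) else
      character()
    bg_sets[[t]] <- bg
    sig_genes <- c(sig_module, bg)
    filler <- setdiff(c(non_module, extra), sig_genes)
    filler <- sort(sample(filler, min(n_filler, length(filler))))
    sig_fdr <- stats::runif(length(sig_genes), 1e-4, 0.049)
    sig_fc <- c(sign_of[sig_module] * stats::runif(length(sig_module), 0.5, 3),
                stats::runif(length(bg), -3, 3))
    fil_fdr <- stats::runif(length(filler), 0.06, 1)
    d <- data.frame(
      gene = c(sig_genes, filler),
      log2fc = c(sig_fc, stats::runif(length(filler), -1, 1)),
      pvalue = c(sig_fdr, fil_fdr) * stats::runif(length(sig_genes) +
                                                    length(filler), 0.1, 1),
      fdr = c(sig_fdr, fil_fdr)
    )
    d <- d[order(d$gene), , drop = FALSE]
    tables[[t]] <- deg_table(d, comparison_label = sprintf("comparison%d", t))
  }
  collisions <- Reduce(intersect, bg_sets)
  attr(tables, "planted_significant") <- sig_module
  attr(tables, "collisions") <- sort(collisions)
  tables
}

#' Generate a random gene-set collection, optionally with a planted set
#'
#' Random sets drawn from the universe; the optional planted set overlaps
#' a caller-given target list at a stated count, which gives enrichment
#' tests a known positive.
#'
#' @param n_sets number of random sets.
#' @param set_size_range length-2 integer range of set sizes.
#' @param universe character vector of genes to draw from.
#' @param planted_genes optional target list the planted set must overlap.
#' @param planted_overlap members of the planted set drawn from
#'   `planted_genes`.
#' @param planted_size total planted set size.
#' @param seed integer seed.
#' @return A `gene_set_collection`; the planted set (if any) is named
#'   `"PLANTED"`.
#' @export
gen_gmt <- function(n_sets = 20L, set_size_range = c(10L, 30L), universe,
                    planted_genes = NULL, planted_overlap = 0L,
                    planted_size = 20L, seed = 1L) {
  if (n_sets < 1L && is.null(planted_genes)) stop("empty collection requested")
  universe <- unique(canonical_symbol(universe))
  stopifnot(length(set_size_range) == 2L,
            set_size_range[1] >= 1L,
            set_size_range[2] <= length(universe))
  set.seed(seed)
  sets <- list()
  for (i in seq_len(n_sets)) {
    k <- sample(seq(set_size_range[1], set_size_range[2]), 1L)
    members <- sort(sample(universe, k))
    attr(members, "description") <- sprintf("random set %d", i)
    sets[[sprintf("SET%03d", i)]] <- members
  }
  if (!is.null(planted_genes)) {
    planted_genes <- unique(canonical_symbol(planted_genes))
    if (planted_overlap > planted_size) {
      stop("requested overlap exceeds the planted set size")
    }
    if (planted_overlap > length(planted_genes)) {
      stop("requested overlap exceeds the target list size")
    }
    inside <- sort(sample(planted_genes, planted_overlap))
    rest_pool <- setdiff(universe, planted_genes)
    outside <- sort(sample(rest_pool,
                           min(planted_size - planted_overlap,
                               length(rest_pool))))
    members <- sort(c(inside, outside))
    attr(members, "description") <- "planted enriched set"
    sets[["PLANTED"]] <- members
  }
  structure(sets, class = "gene_set_collection")
}

#' Generate a synthetic patient cohort with planted prognosis groups
#'
#' Patients are assigned equiprobably to `n_groups` groups. Signature
#' genes carry a group-specific mean pattern: each (gene, group) pair gets
#' a random +/- direction of magnitude `expression_effect` (in SD units of
#' the unit-variance noise). A pattern, rather than a constant shift, is
#' planted because Pearson-correlation distance is location-invariant and
#' only profile-shape differences are detectable by the clustering chain.
#' Non-signature genes are iid Normal(0, 1). Survival times are
#' exponential with hazard `baseline_hazard * hazard_ratios[group]`,
#' subject to independent exponential censoring at `censoring_rate` and
#' administrative censoring at `admin_censor_time`. Optional subtype
#' labels are drawn independently of the prognosis groups. Deterministic
#' per seed.
#'
#' @param n_patients cohort size.
#' @param n_genes total measured genes (>= number of signature genes).
#' @param signature_genes character vector of signature gene names;
#'   default 76 genes named `SIG0001..`.
#' @param n_groups number of planted groups.
#' @param expression_effect between-group mean-shift magnitude (SD units).
#' @param baseline_hazard events per year in the reference group.
#' @param hazard_ratios per-group hazard ratios (length `n_groups`).
#' @param censoring_rate independent censoring hazard per year.
#' @param admin_censor_time administrative censoring horizon (years).
#' @param subtype_labels optional character vector of subtype labels.
#' @param subtype_props mixing proportions for `subtype_labels`.
#' @param seed integer seed.
#' @return List: `expr` (gene-by-patient `expression_matrix`), `survival`
#'   (data.frame `patient`, `time`, `event`, `subtype`), `groups` (named
#'   integer vector of planted group labels), `signature_genes`.
#' @export
gen_cohort <- function(n_patients = 200L, n_genes = 400L,
                       signature_genes = sprintf("SIG%04d", 1:76),
                       n_groups = 2L, expression_effect = 2,
                       baseline_hazard = 0.08, hazard_ratios = c(1, 3),
                       censoring_rate = 0.04, admin_censor_time = 20,
                       subtype_labels = NULL, subtype_props = NULL,
                       seed = 1L) {
  signature_genes <- unique(canonical_symbol(signature_genes))
  stopifnot(n_patients >= 2L, n_groups >= 1L,
            length(hazard_ratios) == n_groups,
            all(hazard_ratios > 0), baseline_hazard > 0,
            censoring_rate >= 0, admin_censor_time > 0,
            expression_effect >= 0,
            n_genes >= length(signature_genes))
  set.seed(seed)
  patients <- sprintf("PT%04d", seq_len(n_patients))
  n_bg <- n_genes - length(signature_genes)
  genes <- c(signature_genes,
             if (n_bg > 0L) sprintf("BG%04d", seq_len(n_bg)))
  groups <- sample.int(n_groups, n_patients, replace = TRUE)
  m <- matrix(stats::rnorm(n_genes * n_patients), nrow = n_genes,
              dimnames = list(genes, patients))
  if (expression_effect > 0 && n_groups > 1L) {
    direction <- matrix(sample(c(-1, 1),
                               length(signature_genes) * n_groups,
                               replace = TRUE),
                        nrow = length(signature_genes))
    m[signature_genes, ] <- m[signature_genes, ] +
      expression_effect * direction[, groups, drop = FALSE]
  }
  rate <- baseline_hazard * hazard_ratios[groups]
  t_event <- stats::rexp(n_patients, rate)
  t_cens <- if (censoring_rate > 0)
    stats::rexp(n_patients, censoring_rate) else rep(Inf, n_patients)
  time <- pmin(t_event, t_cens, admin_censor_time)
  event <- as.integer(t_event <= pmin(t_cens, admin_censor_time))
  subtype <- if (is.null(subtype_labels)) rep("unknown", n_patients) else
    sample(subtype_labels, n_patients, replace = TRUE,
           prob = subtype_props)
  list(expr = expression_matrix(m, row_kind = "gene"),
       survival = data.frame(patient = patients, time = time, event = event,
                             subtype = subtype, stringsAsFactors = FALSE),
       groups = stats::setNames(groups, patients),
       signature_genes = signature_genes)
}

#' Expand a gene-level matrix into probes with a known best probe
#'
#' Each gene row is replicated into 1 or more probe rows with additive
#' Gaussian noise and a probe-specific baseline offset; the probe with the
#' highest planted offset is recorded as ground truth for
#' [collapse_probes()] tests.
#'
#' @param expr gene-level expression matrix.
#' @param probes_per_gene_range length-2 integer range.
#' @param noise_sd per-measurement probe noise SD.
#' @param offset_step spacing of probe baseline offsets (keeps the
#'   top-mean probe unambiguous).
#' @param seed integer seed.
#' @return List: `probe_expr` (probe-level `expression_matrix`), `map`
#'   (named character probe -> gene), `top_probe` (named character
#'   gene -> planted best probe).
#' @export
gen_probe_map <- function(expr, probes_per_gene_range = c(1L, 3L),
                          noise_sd = 0.05, offset_step = 1,
                          seed = 1L) {
  stopifnot(length(probes_per_gene_range) == 2L,
            probes_per_gene_range[1] >= 1L)
  set.seed(seed)
  genes <- rownames(expr)
  rows <- list(); map <- character(); top <- character()
  for (g in genes) {
    k <- sample(seq(probes_per_gene_range[1], probes_per_gene_range[2]), 1L)
    offsets <- sample(seq_len(k)) * offset_step  # distinct -> unique top probe
    ids <- sprintf("%s_AT%d", g, seq_len(k))
    for (j in seq_len(k)) {
      rows[[ids[j]]] <- expr[g, ] + offsets[j] +
        stats::rnorm(ncol(expr), 0, noise_sd)
    }
    map[ids] <- g
    top[g] <- ids[which.max(offsets)]
  }
  probe_expr <- do.call(rbind, rows)
  dimnames(probe_expr) <- list(names(rows), colnames(expr))
  list(probe_expr = expression_matrix(probe_expr, row_kind = "probe"),
       map = map, top_probe = top)
}
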