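#' Map differential targets onto network nodes
#'
#' Targets found in the network become the terminal set that the Steiner
#' tree must span; the rest are reported as unmapped. Matching is exact on
#' uppercased symbols.
#'
#' @param net a `signaling_network`.
#' @param targets character vector of gene symbols (deduplicated internally).
#' @return List with `terminals` and `unmapped`, both sorted character
#'   vectors, class `terminal_set`.
#' @export
map_targets <- function(net, targets) {
  stopifnot(inherits(net, "signaling_network"))
  targets <- unique(canonical_symbol(targets))
  if (length(targets) == 0L) stop("empty target list")
  terminals <- sort(intersect(targets, net$nodes))
  structure(list(terminals = terminals,
                 unmapped = sort(setdiff(targets, net$nodes))),
            class = "terminal_set")
}

# Lexicographically smallest shortest path from `from` to `to`.
# dist_to: distances of every node to `to` (unit weights). Greedy descent on
# the distance field is optimal because any node at distance d-1 admits a
# shortest continuation.
lex_shortest_path <- function(g, from, to, dist_to) {
  path <- from
  cur <- from
  while (cur != to) {
    nb <- igraph::V(g)$name[igraph::neighbors(g, cur)]
    cand <- nb[dist_to[nb] == dist_to[cur] - 1]
    cur <- sort(cand)[1L]
    path <- c(path, cur)
  }
  path
}

# Deterministic Prim MST on a small complete graph given a distance matrix
# with sorted row/col names; ties broken by smallest new-node name, then
# smallest in-tree node name. Returns a 2-column matrix of node-name pairs.
prim_mst_closure <- function(d) {
  nodes <- rownames(d)
  n <- length(nodes)
  if (n == 1L) return(matrix(character(), ncol = 2))
  in_tree <- nodes[1L]
  out <- setdiff(nodes, in_tree)
  edges <- matrix(character(), ncol = 2)
  while (length(out) > 0L) {
    sub <- d[in_tree, out, drop = FALSE]
    best <- min(sub)
    idx <- which(sub == best, arr.ind = TRUE)
    cand <- data.frame(u = in_tree[idx[, 1]], v = out[idx[, 2]])
    cand <- cand[order(cand$v, cand$u), , drop = FALSE]
    pick <- cand[1L, ]
    edges <- rbind(edges, c(pick$u, pick$v))
    in_tree <- c(in_tree, pick$v)
    out <- setdiff(out, pick$v)
  }
  edges
}

# Kruskal MST on a unit-weight edge list (2-column matrix of sorted pairs),
# edges considered in lexicographic order -> deterministic.
kruskal_unit_mst <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    ru <- find(edges[i, 1]); rv <- find(edges[i, 2])
    if (ru != rv) {
      parent[[ru]] <- rv
      keep[i] <- TRUE
    }
  }
  edges[keep, , drop = FALSE]
}

#' Approximate minimum Steiner tree by metric-closure heuristic
#'
#' Classic shortest-path (metric-closure) 2-approximation: (1) build the
#' complete graph on terminals weighted by BFS distance, (2) take its
#' minimum spanning tree, (3) expand each closure edge into one concrete
#' shortest path (lexicographically smallest node sequence among ties),
#' (4) take a spanning tree of the union of those paths, (5) repeatedly
#' prune non-terminal leaves. Every tie is broken by lexicographic node
#' order, so the result is deterministic across runs and platforms. The
#' tree cost is at most 2(1 - 1/|T|) times the optimum.
#'
#' @param g undirected igraph (from [to_undirected()]).
#' @param terminals character vector of terminal node names, all in one
#'   connected component of `g`.
#' @return List with `tree_nodes` (sorted character), `tree_edges`
#'   (2-column character matrix, each row a sorted pair), and
#'   `steiner_nodes` (tree nodes that are not terminals).
#' @export
approx_steiner_tree <- function(g, terminals) {
  stopifnot(igraph::is_igraph(g))
  terminals <- sort(unique(canonical_symbol(terminals)))
  if (length(terminals) == 0L) stop("no terminals supplied")
  missing <- setdiff(terminals, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop("terminal(s) not in graph: ", paste(missing, collapse = ", "))
  }
  comp <- igraph::components(g)
  memb <- comp$membership[terminals]
  if (length(unique(memb)) > 1L) {
    parts <- split(terminals, memb)
    stop("terminals span ", length(parts), " components: ",
         paste(vapply(parts, paste, "", collapse = ","), collapse = " | "))
  }
  if (length(terminals) == 1L) {
    return(list(tree_nodes = terminals,
                tree_edges = matrix(character(), ncol = 2),
                steiner_nodes = character()))
  }
  d <- igraph::distances(g, v = terminals, to = terminals, weights = NA)
  dimnames(d) <- list(terminals, terminals)
  closure_mst <- prim_mst_closure(d)
  # expand closure edges to concrete paths, oriented low -> high name
  path_edges <- matrix(character(), ncol = 2)
  for (i in seq_len(nrow(closure_mst))) {
    uv <- sort(closure_mst[i, ])
    dist_to <- igraph::distances(g, v = uv[2L], weights = NA)[1L, ]
    p <- lex_shortest_path(g, uv[1L], uv[2L], dist_to)
    if (length(p) > 1L) {
      seg <- cbind(p[-length(p)], p[-1L])
      seg <- t(apply(seg, 1L, sort))
      path_edges <- rbind(path_edges, seg)
    }
  }
  path_edges <- unique(path_edges)
  nodes <- sort(unique(c(terminals, as.vector(path_edges))))
  tree_edges <- kruskal_unit_mst(nodes, path_edges)
  # prune non-terminal leaves until fixed point
  repeat {
    deg <- table(factor(as.vector(tree_edges), levels = nodes))
    leaves <- names(deg)[deg == 1L]
    drop <- setdiff(leaves, terminals)
    if (length(drop) == 0L) break
    keep_row <- !(tree_edges[, 1] %in% drop | tree_edges[, 2] %in% drop)
    tree_edges <- tree_edges[keep_row, , drop = FALSE]
    nodes <- setdiff(nodes, drop)
  }
  tree_edges <- tree_edges[order(tree_edges[, 1], tree_edges[, 2]), ,
                           drop = FALSE]
  list(tree_nodes = nodes, tree_edges = tree_edges,
       steiner_nodes = setdiff(nodes, terminals))
}

#' Exact minimum Steiner tree by exhaustive enumeration
#'
#' Test oracle for [approx_steiner_tree()]: enumerates subsets of
#' non-terminal nodes in increasing size and returns the first node set
#' whose induced subgraph is connected and contains all terminals. A tree
#' on k nodes has k - 1 edges, so the smallest connected superset of the
#' terminals gives the minimum-edge-count Steiner tree. Only feasible for
#' small graphs.
#'
#' @param g undirected igraph with at most `max_nodes` vertices.
#' @param terminals character vector of terminal node names.
#' @param max_nodes enumeration guard (default 16).
#' @return List with `tree_nodes`, `tree_edges`, `cost` (edge count).
#' @export
exact_steiner_tree <- function(g, terminals, max_nodes = 16L) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  if (n > max_nodes) {
    stop("exact enumeration limited to graphs with <= ", max_nodes, " nodes")
  }
  terminals <- sort(unique(canonical_symbol(terminals)))
  if (length(terminals) == 0L) stop("no terminals supplied")
  others <- sort(setdiff(igraph::V(g)$name, terminals))
  for (k in 0:length(others)) {
    combos <- if (k == 0L) list(character()) else
      utils::combn(others, k, simplify = FALSE)
    best <- NULL
    for (s in combos) {
      cand <- c(terminals, s)
      sub <- igraph::induced_subgraph(g, cand)
      if (igraph::vcount(sub) > 0L && igraph::is_connected(sub)) {
        best <- cand
        break
      }
    }
    if (!is.null(best)) {
      sub <- igraph::induced_subgraph(g, best)
      el <- igraph::as_edgelist(sub)
      el <- if (nrow(el) > 0L) t(apply(el, 1L, sort)) else
        matrix(character(), ncol = 2)
      tree_edges <- kruskal_unit_mst(sort(best), el)
      return(list(tree_nodes = sort(best), tree_edges = tree_edges,
                  cost = nrow(tree_edges)))
    }
  }
  stop("terminals are not connected in the graph")
}

#' Extract the differential pathway module from a network and a DEG table
#'
#' End-to-end module induction: map the significant targets onto the
#' network, connect the mapped terminals with the metric-closure Steiner
#' heuristic (run per connected component when terminals are split across
#' components), then induce the signed directed subnetwork on all tree
#' nodes. Terminals carry their log2 fold-change annotation; Steiner nodes
#' carry none. A display copy of the annotation clamps fold-changes to
#' +/- 2 for color scaling; the raw values are kept.
#'
#' @param net a `signaling_network`.
#' @param targets a DEG table (data.frame with `gene`, `log2fc` and
#'   optionally `fdr`) or a plain targets data.frame with `gene`, `log2fc`.
#'   When an `fdr` column is present only rows with `fdr < fdr_threshold`
#'   are used.
#' @param fdr_threshold significance cutoff applied when `targets` has an
#'   `fdr` column (default 0.05).
#' @param clamp display clamp for fold-changes (default 2).
#' @return Object of class `steiner_module`: `terminals`, `steiner_nodes`,
#'   `tree_edges`, `subnetwork` (a `signaling_network`), `annotation` and
#'   `display_annotation` (named numeric vectors, `NA` for Steiner nodes),
#'   `unmapped`, and `counts`.
#' @export
build_module <- function(net, targets, fdr_threshold = 0.05, clamp = 2) {
  stopifnot(inherits(net, "signaling_network"), is.data.frame(targets),
            all(c("gene", "log2fc") %in% names(targets)))
  if ("fdr" %in% names(targets)) {
    targets <- targets[targets$fdr < fdr_threshold, , drop = FALSE]
  }
  if (nrow(targets) == 0L) stop("no significant target genes")
  genes <- canonical_symbol(targets$gene)
  fc <- stats::setNames(targets$log2fc, genes)[!duplicated(genes)]
  ts <- map_targets(net, genes)
  if (length(ts$terminals) == 0L) {
    stop("none of the ", length(genes), " target genes map to the network")
  }
  und <- to_undirected(net)
  comp <- igraph::components(und)
  groups <- split(ts$terminals, comp$membership[ts$terminals])
  tree_nodes <- character()
  tree_edges <- matrix(character(), ncol = 2)
  for (grp in groups) {
    tr <- approx_steiner_tree(und, grp)
    tree_nodes <- c(tree_nodes, tr$tree_nodes)
    tree_edges <- rbind(tree_edges, tr$tree_edges)
  }
  tree_nodes <- sort(unique(tree_nodes))
  sub <- induced_subgraph(net, tree_nodes)
  steiner_nodes <- setdiff(tree_nodes, ts$terminals)
  ann <- stats::setNames(rep(NA_real_, length(tree_nodes)), tree_nodes)
  ann[ts$terminals] <- fc[ts$terminals]
  disp <- pmin(pmax(ann, -clamp), clamp)
  structure(list(
    terminals = ts$terminals,
    steiner_nodes = sort(steiner_nodes),
    tree_edges = tree_edges[order(tree_edges[, 1], tree_edges[, 2]), ,
                            drop = FALSE],
    subnetwork = sub,
    annotation = ann,
    display_annotation = disp,
    unmapped = ts$unmapped,
    counts = c(terminals = length(ts$terminals),
               steiner = length(steiner_nodes),
               total = length(tree_nodes))
  ), class = "steiner_module")
}

#' @export
print.steiner_module <- function(x, ...) {
  cat(sprintf(
    "steiner_module: %d terminals + %d Steiner nodes = %d module nodes, %d signed edges\n",
    x$counts[["terminals"]], x$counts[["steiner"]], x$counts[["total"]],
    nrow(x$subnetwork$edges)))
  if (length(x$unmapped) > 0L) {
    cat(sprintf("  %d target gene(s) not on the network\n", length(x$unmapped)))
  }
  invisible(x)
}

#' Export a Steiner module as node and edge tables
#'
#' Writes `nodes.tsv` (gene, role, log2fc, clamped display value) and
#' `edges.tsv` (source, relation, target) under `dir`.
#'
#' @param module a `steiner_module`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_module <- function(module, dir) {
  stopifnot(inherits(module, "steiner_module"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- data.frame(
    gene = names(module$annotation),
    role = ifelse(names(module$annotation) %in% module$terminals,
                  "terminal", "steiner"),
    log2fc = unname(module$annotation),
    log2fc_display = unname(module$display_annotation)
  )
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  e <- module$subnetwork$edges
  utils::write.table(
    data.frame(source = e$source, relation = e$sign, target = e$target),
    file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
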