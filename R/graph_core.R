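#' Construct a signed directed signaling network
#'
#' A signaling network is a directed graph whose nodes are gene symbols and
#' whose edges carry a regulatory sign (`"activation"` or `"inhibition"`).
#' Symbols are canonicalized to uppercase on ingest so that network nodes,
#' differential-expression tables and expression-matrix rows match exactly.
#'
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (`"activation"` or `"inhibition"`). May have zero rows.
#' @param nodes optional character vector of node symbols; defaults to the
#'   union of edge endpoints. Isolated nodes are allowed.
#' @param name free-text network label.
#' @param allow_self_loops if `FALSE` (default), self-edges are an error.
#' @return An object of class `signaling_network`: a list with elements
#'   `nodes` (sorted character vector), `edges` (data.frame `source`,
#'   `target`, `sign`) and `name`.
#' @export
signaling_network <- function(edges = NULL, nodes = NULL, name = "network",
                              allow_self_loops = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "sign") %in% names(edges)))
  edges <- data.frame(source = canonical_symbol(edges$source),
                      target = canonical_symbol(edges$target),
                      sign   = as.character(edges$sign),
                      stringsAsFactors = FALSE)
  bad_sign <- setdiff(unique(edges$sign), c("activation", "inhibition"))
  if (length(bad_sign) > 0L) {
    stop("unknown relation token(s): ", paste(bad_sign, collapse = ", "))
  }
  if (!allow_self_loops && any(edges$source == edges$target)) {
    loops <- unique(edges$source[edges$source == edges$target])
    stop("self-loop(s) rejected (allow_self_loops = FALSE): ",
         paste(loops, collapse = ", "))
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    n_sign <- tapply(edges$sign[dup], key[dup], function(s) length(unique(s)))
    if (any(n_sign > 1L)) {
      conflicted <- names(n_sign)[n_sign > 1L]
      stop("conflicting signs for edge(s): ",
           paste(gsub("\r", " -> ", conflicted), collapse = ", "))
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  if (is.null(nodes)) {
    nodes <- union(edges$source, edges$target)
  } else {
    nodes <- union(canonical_symbol(nodes), union(edges$source, edges$target))
  }
  nodes <- sort(unique(nodes))
  if (length(nodes) < 1L) stop("network must contain at least one node")
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, name = name),
            class = "signaling_network")
}

canonical_symbol <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(x == "" | grepl("\\s", x))) {
    stop("gene symbols must be non-empty and whitespace-free")
  }
  x
}

#' @export
print.signaling_network <- function(x, ...) {
  cat(sprintf("signaling_network '%s': %d nodes, %d signed directed edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    cat(sprintf("  activation: %d, inhibition: %d\n",
                sum(x$edges$sign == "activation"),
                sum(x$edges$sign == "inhibition")))
  }
  invisible(x)
}

#' Read a signed network from a SIF-style file
#'
#' Each non-comment line is `source<TAB>relation<TAB>target` with relation
#' one of `activation`, `inhibition`. Lines starting with `#` are skipped;
#' duplicate identical lines are deduplicated; symbols are uppercased.
#'
#' @param path path to the SIF file.
#' @param name network label; defaults to the file name.
#' @param allow_self_loops passed to [signaling_network()].
#' @return A `signaling_network`.
#' @export
read_sif <- function(path, name = basename(path), allow_self_loops = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  iso <- sub("^# node\t", "", lines[grepl("^# node\t", lines)])
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L && length(iso) == 0L) {
    stop("no network lines in ", path, " (node count >= 1 violated)")
  }
  if (length(keep) == 0L) {
    return(signaling_network(nodes = iso, name = name,
                             allow_self_loops = allow_self_loops))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields != 3L)) {
    bad <- keep[which(n_fields != 3L)[1L]]
    stop(sprintf("malformed line %d in %s: expected 3 tab-separated fields",
                 bad, path))
  }
  m <- do.call(rbind, parts)
  signaling_network(
    edges = data.frame(source = m[, 1], target = m[, 3], sign = m[, 2],
                       stringsAsFactors = FALSE),
    nodes = if (length(iso) > 0L) iso else NULL,
    name = name, allow_self_loops = allow_self_loops
  )
}

#' Write a signed network to a SIF-style file
#'
#' Inverse of [read_sif()]; edges are written in sorted order so output is
#' byte-deterministic for a given network.
#'
#' @param net a `signaling_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "signaling_network"))
  e <- net$edges
  lines <- sprintf("%s\t%s\t%s", e$source, e$sign, e$target)
  iso <- setdiff(net$nodes, union(e$source, e$target))
  if (length(iso) > 0L) {
    # isolated nodes kept as comment so the round trip preserves the node set
    lines <- c(lines, sprintf("# node\t%s", iso))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Collapse a signed directed network to an undirected unweighted graph
#'
#' One undirected edge per unordered node pair that has at least one directed
#' edge in either orientation; signs are discarded, the node set is kept.
#' This undirected view is the search space for the Steiner-tree step.
#'
#' @param net a `signaling_network`.
#' @return An undirected [igraph::igraph] with the network's nodes.
#' @export
to_undirected <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = net$nodes)
  )
  igraph::as_undirected(g, mode = "collapse")
}

#' Induce the signed directed subnetwork on a node subset
#'
#' Keeps exactly the original directed signed edges with both endpoints in
#' `keep`; this is how the Steiner-tree node set is turned back into a
#' signed module.
#'
#' @param net a `signaling_network`.
#' @param keep character vector of node symbols, a subset of `net$nodes`.
#' @return A `signaling_network` on `keep`.
#' @export
induced_subgraph <- function(net, keep) {
  stopifnot(inherits(net, "signaling_network"))
  keep <- unique(canonical_symbol(keep))
  missing <- setdiff(keep, net$nodes)
  if (length(missing) > 0L) {
    stop("node(s) not in network: ", paste(sort(missing), collapse = ", "))
  }
  e <- net$edges
  e <- e[e$source %in% keep & e$target %in% keep, , drop = FALSE]
  signaling_network(edges = e, nodes = keep,
                    name = paste0(net$name, " (induced)"),
                    allow_self_loops = TRUE)
}

#' Breadth-first shortest-path lengths from a set of source nodes
#'
#' Unit-weight distances on an undirected graph; unreachable nodes get `Inf`.
#'
#' @param g an undirected igraph (e.g. from [to_undirected()]).
#' @param sources character vector of source node names.
#' @return Numeric matrix, rows = sources, columns = all graph nodes.
#' @export
shortest_path_lengths <- function(g, sources) {
  stopifnot(igraph::is_igraph(g))
  sources <- unique(canonical_symbol(sources))
  missing <- setdiff(sources, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop("source node(s) not in graph: ", paste(missing, collapse = ", "))
  }
  d <- igraph::distances(g, v = sources, to = igraph::V(g), weights = NA)
  dimnames(d) <- list(sources, igraph::V(g)$name)
  d
}
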