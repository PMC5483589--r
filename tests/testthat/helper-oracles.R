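# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: direct enumeration, closed-form combinatorics and
# naive O(n^3) re-implementations.

# P(overlap >= k) for drawing n genes from a universe of N containing K set
# members, by direct combinatorial summation of the hypergeometric pmf.
oracle_hyper_tail <- function(N, K, n, k) {
  kk <- seq(max(0L, k), min(K, n))
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Literal enumeration of every possible draw (for small cases only).
oracle_hyper_enum <- function(universe, gene_set, list_size, observed) {
  draws <- utils::combn(universe, list_size)
  hits <- apply(draws, 2L, function(d) sum(d %in% gene_set))
  mean(hits >= observed)
}

# Benjamini-Hochberg step-up from its definition: q_(i) = min_{j >= i}
# m * p_(j) / j, capped at 1, mapped back to the input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, rev(cummin(rev(m * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

# Naive complete-linkage agglomeration: merge the pair of clusters with the
# smallest maximum inter-member distance, record heights.
oracle_complete_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# k-sample log-rank chi-square from the observed-minus-expected risk-table
# tabulation (hypergeometric variance at each event time).
oracle_logrank_chisq <- function(time, event, group) {
  group <- factor(group)
  G <- nlevels(group)
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- rep(0, G)
  V <- matrix(0, G, G)
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    dg <- vapply(levels(group), function(g)
      sum(event == 1 & time == t & group == g), numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      for (i in 1:G) for (j in 1:G) {
        V[i, j] <- V[i, j] +
          d * (ng[i] / n) * ((i == j) - ng[j] / n) * (n - d) / (n - 1)
      }
    }
  }
  v <- (O - E)[-1]
  drop(t(v) %*% solve(V[-1, -1, drop = FALSE]) %*% v)
}

# All-pairs shortest paths by Floyd-Warshall on an unweighted undirected
# adjacency matrix.
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Random undirected test graph as an igraph with uppercase node names;
# returns the largest connected component.
random_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(stats::runif(n * n) < p, n, n)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  el <- which(adj, arr.ind = TRUE)
  nodes <- sprintf("N%02d", seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]]),
    directed = FALSE, vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  igraph::induced_subgraph(
    g, names(comp$membership)[comp$membership == which.max(comp$csize)])
}

# Small signed network shared by several tests.
toy_network <- function() {
  signaling_network(data.frame(
    source = c("A", "B", "C", "C", "D"),
    target = c("B", "C", "A", "D", "E"),
    sign = c("activation", "inhibition", "activation", "activation",
             "inhibition")))
}

# Distance matrix with two well-separated planted groups.
planted_two_group_dist <- function(n_per_group, seed, within = 0.2,
                                   between = 1.5, jitter = 0.02) {
  set.seed(seed)
  n <- 2L * n_per_group
  lab <- rep(1:2, each = n_per_group)
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    base <- if (lab[i] == lab[j]) within else between
    d[i, j] <- d[j, i] <- base + stats::runif(1, 0, jitter)
  }
  dimnames(d) <- list(sprintf("P%02d", 1:n), sprintf("P%02d", 1:n))
  list(dist = d, labels = lab)
}
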