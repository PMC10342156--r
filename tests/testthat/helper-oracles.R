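# Independent oracles used across the suite. Deliberately naive: direct
# sums, exhaustive enumeration, BFS by hand -- never the package's own path.

# Plain direct-sum hypergeometric upper tail: sum of pmf terms from i = r.
oracle_hyper_tail <- function(m, t, n, r) {
  if (r == 0) return(1)
  i <- r:min(t, n)
  sum(choose(t, i) * choose(m - t, n - i)) / choose(m, n)
}

# All-pairs shortest-path distances by repeated BFS over an edge list.
oracle_distances <- function(nodes, edges) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v) character(0))
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (src in nodes) {
    d[src, src] <- 0
    frontier <- src
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- setdiff(unique(unlist(adj[frontier])),
                     nodes[d[src, ] < Inf])
      d[src, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

# Brute-force distance-k clique subpathways: every subset (bitmask), keep
# those with all pairwise distances <= k, then drop non-maximal ones.
oracle_k_clique <- function(nodes, edges, k, min_size = 3) {
  n <- length(nodes)
  d <- oracle_distances(nodes, edges)
  ok <- d <= k
  masks <- integer(0)
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0)
    if (all(ok[idx, idx])) masks <- c(masks, mask)
  }
  maximal <- vapply(masks, function(m)
    !any(masks != m & bitwAnd(masks, m) == m), TRUE)
  sets <- lapply(masks[maximal], function(mask)
    sort(nodes[which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0)]))
  sets[lengths(sets) >= min_size]
}

random_pathway_graph <- function(id, n_nodes, edge_prob) {
  nodes <- sprintf("g%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < edge_prob
  list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
}

# Minimal hand-built ExpressionMatrix: genes x cells values with one
# lineage and two stages unless overridden.
toy_matrix <- function(values, biotype = NULL, lineage = NULL, stage = NULL) {
  g <- nrow(values); n <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("G%02d", 1:g)
  if (is.null(colnames(values))) colnames(values) <- sprintf("c%02d", 1:n)
  if (is.null(biotype)) biotype <- rep("protein_coding", g)
  if (is.null(lineage)) lineage <- rep("follicle", n)
  if (is.null(stage)) stage <- rep(c("primordial", "primary"), length.out = n)
  expression_matrix(values, biotype, lineage, stage)
}
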