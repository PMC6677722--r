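# Small graph fixtures built in code.

graph_from_edges <- function(...) {
  igraph::graph_from_edgelist(
    matrix(c(...), ncol = 2, byrow = TRUE), directed = FALSE)
}

# path A - B - C - D
path_graph <- function() graph_from_edges("A","B", "B","C", "C","D")

# triangle plus an isolated pair
two_component_graph <- function() {
  graph_from_edges("A","B", "B","C", "A","C", "X","Y")
}

random_graph <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# independent reachability-closure component oracle (no igraph machinery)
brute_components <- function(edges, nodes) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      if (!(a %in% nodes) || !(b %in% nodes)) next
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[c(a, b)] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

# Floyd-Warshall all-pairs oracle on an edge matrix
brute_distances <- function(edges, nodes) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    d[edges[i, 1], edges[i, 2]] <- 1
    d[edges[i, 2], edges[i, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}
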