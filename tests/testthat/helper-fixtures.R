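# Shared small fixtures for the unit tests.

# A deterministic prior graph: path a-b-c-d plus chord b-d and isolated "e".
fixtureGraph <- function() {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c("a", "b", "c", "d", "e"))
  igraph::add_edges(g, c("a", "b", "b", "c", "c", "d", "b", "d"))
}

# Random connected-ish Erdos-Renyi graph over p named genes.
fixtureRandomGraph <- function(p, nEdges, seed) {
  set.seed(seed)
  genes <- paste0("g", sprintf("%02d", seq_len(p)))
  A <- matrix(0, p, p)
  pick <- sample(which(upper.tri(A)), nEdges)
  A[pick] <- 1
  A <- A + t(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- genes
  g
}

# Small expression fixture: p genes, n samples, mild correlation structure.
fixtureExpression <- function(p = 6, n = 80, seed = 42) {
  set.seed(seed)
  genes <- paste0("g", sprintf("%02d", seq_len(p)))
  Z <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, genes))
  Z[, 2] <- 0.6 * Z[, 1] + 0.8 * Z[, 2]
  rownames(Z) <- paste0("s", seq_len(n))
  Z
}

# Complete prior over a gene set (every pair connected).
fixtureCompletePrior <- function(genes, damping = 0.85) {
  g <- igraph::make_full_graph(length(genes))
  igraph::V(g)$name <- genes
  priorScores(g, genes, damping = damping)
}
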