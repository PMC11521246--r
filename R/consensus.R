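#' Build an unweighted gene network from an edge test table
#'
#' Nodes are the full analysis gene list (isolated genes included, so that
#' density denominators use all pairs); edges are the significant calls of a
#' [significantEdges()] (or [differentialEdges()]) table.
#'
#' @param table edge table with `geneA`, `geneB` and a logical `significant`
#'   column (rows already filtered to significant ones are also accepted).
#' @param genes character vector: the full node set.
#' @return an undirected simple `igraph` graph.
#' @export
geneNetwork <- function(table, genes) {
  if (!is.null(table$significant)) table <- table[table$significant, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(genes)
  if (nrow(table)) {
    if (!all(c(table$geneA, table$geneB) %in% genes))
      stop("edge endpoints must be in the gene list")
    g <- igraph::add_edges(g, rbind(table$geneA, table$geneB))
  }
  igraph::simplify(g)
}

#' Density and largest-connected-component size of a gene network
#'
#' @param net an `igraph` graph.
#' @return list with `density` (edges over all `N(N-1)/2` pairs) and
#'   `largestComponent` (node count of the largest connected component).
#' @export
networkStats <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop("density is undefined for fewer than 2 nodes")
  comp <- igraph::components(net)
  list(density = igraph::ecount(net) / (n * (n - 1) / 2),
       largestComponent = max(comp$csize))
}

#' Modularity of a network partition
#'
#' Evaluates \eqn{Q = \sum_c [L_c/m - (k_c/2m)^2]} over communities `c`,
#' where `m` is the edge count, `L_c` the intra-community edge count and
#' `k_c` the total degree of community `c`. `Q` lies in `[-1, 1]`; an
#' edgeless network returns 0 by convention.
#'
#' @param net an `igraph` graph.
#' @param membership community id per node (named by node, or in
#'   `V(net)` order).
#' @return modularity value `Q`.
#' @export
modularityScore <- function(net, membership) {
  nodes <- igraph::V(net)$name
  if (!is.null(names(membership))) {
    if (!all(nodes %in% names(membership)))
      stop("membership must cover all nodes")
    membership <- membership[nodes]
  }
  if (length(membership) != length(nodes))
    stop("membership must cover all nodes")
  m <- igraph::ecount(net)
  if (m == 0) {
    message("modularityScore: empty edge set, Q = 0 by convention")
    return(0)
  }
  el <- igraph::as_edgelist(net, names = FALSE)
  deg <- igraph::degree(net)
  Q <- 0
  for (cc in unique(membership)) {
    inC <- which(membership == cc)
    Lc <- sum(el[, 1] %in% inC & el[, 2] %in% inC)
    kc <- sum(deg[inC])
    Q <- Q + Lc / m - (kc / (2 * m))^2
  }
  Q
}

#' Greedy modularity-maximization clustering (Clauset-Newman-Moore)
#'
#' Partitions the network into communities by CNM greedy agglomeration
#' (via [igraph::cluster_fast_greedy()]). An edgeless network yields
#' singleton communities with `Q = 0`.
#'
#' @param net an `igraph` graph (simple, undirected).
#' @return list with `membership` (named integer vector) and `Q`.
#' @export
clusterModularity <- function(net) {
  nodes <- igraph::V(net)$name
  if (igraph::ecount(net) == 0) {
    memb <- stats::setNames(seq_along(nodes), nodes)
    return(list(membership = memb, Q = 0))
  }
  cl <- igraph::cluster_fast_greedy(igraph::simplify(net))
  memb <- stats::setNames(as.integer(igraph::membership(cl)), nodes)
  list(membership = memb, Q = modularityScore(net, memb))
}

#' Module co-occurrence counts across partitions
#'
#' Counts, for every gene pair, the number of partitions in which the two
#' genes share a community. The diagonal equals the partition count.
#'
#' @param partitions list of membership vectors (all named over the same
#'   gene set) or of [clusterModularity()] results.
#' @return symmetric integer gene x gene matrix.
#' @export
coOccurrence <- function(partitions) {
  if (length(partitions) == 0) stop("need at least one partition")
  memb <- lapply(partitions, function(p) if (is.list(p)) p$membership else p)
  genes <- sort(names(memb[[1]]))
  C <- matrix(0L, length(genes), length(genes), dimnames = list(genes, genes))
  for (m in memb) {
    if (!setequal(names(m), genes)) stop("partitions must share one node set")
    m <- m[genes]
    same <- outer(m, m, "==")
    C <- C + same
  }
  storage.mode(C) <- "integer"
  C
}

#' Consensus gene clusters from the co-occurrence matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - C/R` (R = number of partitions), cut at `k` clusters (default 10).
#'
#' @param C co-occurrence matrix from [coOccurrence()].
#' @param k number of clusters.
#' @param nPartitions number of partitions `R`; defaults to `max(diag(C))`.
#' @return named integer vector of cluster ids.
#' @export
consensusClusters <- function(C, k = 10, nPartitions = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(C)) stop("k exceeds the number of genes")
  if (is.null(nPartitions)) nPartitions <- max(diag(C))
  D <- 1 - C / nPartitions
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  stats::cutree(hc, k = k)
}

#' Poisson significance of gene co-clustering
#'
#' Compares each pair's observed co-occurrence count to a Poisson null whose
#' rate is the expected number of co-clusterings under random assignment:
#' \eqn{\lambda = \sum_r \sum_c (n_{r,c}/N)^2}, summing each partition's
#' squared cluster-size proportions. The p-value is the Poisson upper tail
#' at the observed count; q-values are BH-adjusted (study FDR 0.05).
#'
#' @param C co-occurrence matrix.
#' @param partitions the partitions that produced `C` (for cluster sizes).
#' @param fdr BH threshold for the significance flag.
#' @return data.frame per unordered pair: observed count, null rate, p, q,
#'   significant.
#' @export
coClusterSignificance <- function(C, partitions, fdr = 0.05) {
  memb <- lapply(partitions, function(p) if (is.list(p)) p$membership else p)
  N <- nrow(C)
  lambda <- sum(vapply(memb, function(m) sum((table(m) / N)^2), 0))
  pt_ <- .pairTable(rownames(C))
  obs <- C[cbind(pt_$i, pt_$j)]
  pv <- stats::ppois(obs - 1, lambda, lower.tail = FALSE)
  q <- bhAdjust(pv)
  data.frame(geneA = pt_$geneA, geneB = pt_$geneB, observed = obs,
             rate = lambda, p = pv, q = q, significant = q <= fdr,
             stringsAsFactors = FALSE)
}
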