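#' Load a prior interaction graph from a two-column edge list
#'
#' Reads a plain-text edge list (two whitespace- or tab-delimited gene-id
#' columns) into a simple undirected [igraph::igraph] object. Duplicate
#' edges (in either orientation) are collapsed and self-loops are dropped
#' with a message reporting the count.
#'
#' @param path path to the edge-list file.
#' @param header logical; set `TRUE` if the file carries a header row.
#' @return an undirected simple `igraph` graph.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B A", "A A", "B C"), f)
#' g <- loadPriorGraph(f)
#' igraph::vcount(g); igraph::ecount(g)
#' @export
loadPriorGraph <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (header) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad))
    stop("malformed edge-list line ", bad[1L] + as.integer(header),
         " in ", path, ": expected two columns")
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  loops <- a == b
  if (any(loops))
    message("loadPriorGraph: dropped ", sum(loops), " self-loop(s)")
  a2 <- a[!loops]; b2 <- b[!loops]
  if (length(a2) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(unique(c(a, b)))
    return(g)
  }
  g <- igraph::graph_from_edgelist(cbind(a2, b2), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Personalized PageRank on the prior graph
#'
#' Stationary distribution of a random walk that, with probability
#' `1 - damping`, restarts to the uniform distribution over `seeds`.
#' Scores are a probability distribution over all graph nodes.
#'
#' @param graph an undirected `igraph` graph.
#' @param seeds character vector of seed genes; must all be graph nodes.
#' @param damping continuation probability of the walk, in (0, 1).
#' @return named numeric vector of scores over all graph nodes (sums to 1).
#' @export
personalizedPageRank <- function(graph, seeds, damping = 0.85) {
  if (damping <= 0 || damping >= 1) stop("damping must be in (0, 1)")
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L || !all(seeds %in% nodes))
    stop("all seeds must be nodes of the prior graph")
  reset <- as.numeric(nodes %in% seeds)
  pr <- igraph::page_rank(graph, personalized = reset, damping = damping,
                          directed = FALSE)$vector
  names(pr) <- nodes
  pr
}

#' Single-seed PageRank score matrix over an analysis gene universe
#'
#' Computes, for each gene of `genes`, its single-seed personalized PageRank
#' vector on `graph`, restricted to the universe. Genes absent from the graph
#' receive an all-zero row (and zero column entries); downstream they obtain
#' infinite regularization and can never act as controlling genes.
#'
#' @param graph prior `igraph` graph.
#' @param genes character vector: the analysis gene universe.
#' @param damping PageRank damping factor (default 0.85).
#' @return a [PriorScores-class] object.
#' @export
priorScores <- function(graph, genes, damping = 0.85) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene universe must be unique")
  nodes <- igraph::V(graph)$name
  inGraph <- genes %in% nodes
  scores <- matrix(0, length(genes), length(genes),
                   dimnames = list(genes, genes))
  for (g in genes[inGraph]) {
    pr <- personalizedPageRank(graph, g, damping)
    keep <- intersect(names(pr), genes)
    scores[g, keep] <- pr[keep]
  }
  new("PriorScores", scores = scores, genes = genes,
      inGraph = stats::setNames(inGraph, genes), damping = damping)
}

#' Pair-specific regularization vector from prior scores
#'
#' For a seed pair \eqn{(i, j)} the penalty on candidate controlling gene
#' \eqn{k} is the reciprocal of its personalized PageRank score under restart
#' mass split equally over the two seeds; genes with zero score (absent or
#' unreachable in the prior) get `Inf` and are never selected as controls.
#' The vector is symmetric in the seed pair and excludes the seeds themselves
#' (their regression coefficients are constrained to zero).
#'
#' @param prior a [PriorScores-class] object.
#' @param geneI,geneJ the seed gene pair (order irrelevant).
#' @return named numeric penalty vector over the universe minus the pair.
#' @export
regularizationVector <- function(prior, geneI, geneJ) {
  genes <- prior@genes
  if (!all(c(geneI, geneJ) %in% genes))
    stop("both genes must be in the analysis universe")
  s <- (prior@scores[geneI, ] + prior@scores[geneJ, ]) / 2
  s <- s[setdiff(genes, c(geneI, geneJ))]
  lam <- ifelse(s > 0, 1 / s, Inf)
  lam
}

#' Select and normalize the controlling-gene penalties
#'
#' Keeps the `nGenes` finite-penalty genes with smallest penalty (ties broken
#' by lexicographic gene id) and rescales them multiplicatively so the
#' minimum equals `minLambda`; `minLambda = 0` sets every selected penalty to
#' zero, recovering the unpenalized regression. If fewer than `nGenes`
#' finite-penalty genes exist, all of them are used with a warning.
#'
#' @param lam named penalty vector as from [regularizationVector()].
#' @param minLambda non-negative scalar target for the minimum penalty.
#' @param nGenes number of controlling genes to select (>= 0).
#' @return named numeric vector of normalized penalties over the selected
#'   controlling genes (length `min(nGenes, available)`).
#' @export
normalizeRegularization <- function(lam, minLambda, nGenes) {
  if (nGenes < 0) stop("nGenes must be >= 0")
  if (minLambda < 0) stop("minLambda must be >= 0")
  if (nGenes == 0) return(stats::setNames(numeric(0), character(0)))
  fin <- lam[is.finite(lam)]
  if (length(fin) < nGenes) {
    warning("only ", length(fin), " finite-penalty genes available (asked ",
            nGenes, "); using all")
    nGenes <- length(fin)
  }
  if (nGenes == 0) return(stats::setNames(numeric(0), character(0)))
  ord <- order(fin, names(fin), method = "radix")
  sel <- fin[ord[seq_len(nGenes)]]
  if (minLambda == 0) return(sel * 0)
  sel * (minLambda / min(sel))
}

#' Expected-degree (Chung-Lu) randomization of the prior graph
#'
#' Draws a random simple graph on the same node set in which each pair
#' \eqn{(u, v)} is an edge independently with probability
#' \eqn{\min(1, d_u d_v / 2m)}, so that expected degrees match the input
#' degree sequence.
#'
#' @param graph prior `igraph` graph.
#' @param seed integer RNG seed for reproducibility.
#' @return a randomized `igraph` graph on the same nodes.
#' @export
randomizeGraphDegree <- function(graph, seed = NULL) {
  if (igraph::vcount(graph) == 0L) stop("graph must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  deg <- igraph::degree(graph)
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_along(deg))
  m2 <- sum(deg)
  empty <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (m2 == 0) return(empty)
  idx <- which(deg > 0)
  pairs <- utils::combn(idx, 2)
  p <- pmin(1, deg[pairs[1, ]] * deg[pairs[2, ]] / m2)
  keep <- stats::runif(length(p)) < p
  if (!any(keep)) return(empty)
  el <- cbind(nodes[pairs[1, keep]], nodes[pairs[2, keep]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g + igraph::vertices(setdiff(nodes, igraph::V(g)$name))
}

#' Row-wise randomization of the PageRank score matrix
#'
#' Permutes, within each row, the scores across controlling-gene positions:
#' the PageRank vector used for each gene keeps its value distribution, but
#' each controlling gene gets a random score. This is the "randomized prior"
#' control used to check that the prior's topology (not just its value
#' distribution) carries information.
#'
#' @param prior a [PriorScores-class] object (or a square score matrix).
#' @param seed integer RNG seed.
#' @return object of the same type with rows permuted.
#' @export
randomizePriorRows <- function(prior, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mat <- if (is(prior, "PriorScores")) prior@scores else prior
  if (nrow(mat) != ncol(mat)) stop("score table must be square")
  out <- mat
  for (r in seq_len(nrow(mat))) out[r, ] <- mat[r, sample.int(ncol(mat))]
  if (is(prior, "PriorScores")) {
    p <- prior
    p@scores <- out
    p
  } else out
}
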