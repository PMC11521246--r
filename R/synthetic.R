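#' Construct a Gaussian graphical model with planted partial correlations
#'
#' Builds a unit-diagonal precision matrix `Omega = I - strength * A` over
#' the chosen edge set, so that the implied partial correlation equals
#' `strength` exactly on every planted edge and 0 elsewhere. The model is
#' positive definite iff `strength < 1/lambda_max(A)`; infeasible
#' combinations raise an error suggesting a lower strength.
#'
#' @param genes gene count (ids `g1..gp`) or character vector of ids.
#' @param edges two-column matrix/data.frame of gene-id pairs, or `NULL` to
#'   draw random edges at `density`.
#' @param density expected fraction of pairs carrying a direct edge, used
#'   when `edges` is `NULL`.
#' @param strength implied partial-correlation magnitude on edges, in (0, 1).
#' @param seed RNG seed for random edge draws.
#' @return a [GroundTruthModel-class].
#' @export
makePrecision <- function(genes, edges = NULL, density = 0.05,
                          strength = 0.4, seed = NULL) {
  if (strength <= 0 || strength >= 1) stop("strength must be in (0, 1)")
  if (is.numeric(genes) && length(genes) == 1L)
    genes <- paste0("g", seq_len(genes))
  p <- length(genes)
  A <- matrix(0, p, p, dimnames = list(genes, genes))
  if (is.null(edges)) {
    if (!is.null(seed)) set.seed(seed)
    ut <- which(upper.tri(A))
    pick <- ut[stats::runif(length(ut)) < density]
    A[pick] <- 1
    A <- A + t(A)
    ij <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    edges <- cbind(genes[ij[, 1]], genes[ij[, 2]])
  } else {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    if (!all(edges %in% genes)) stop("edge endpoints must be in genes")
    for (r in seq_len(nrow(edges)))
      A[edges[r, 1], edges[r, 2]] <- A[edges[r, 2], edges[r, 1]] <- 1
  }
  omega <- diag(p) - strength * A
  dimnames(omega) <- list(genes, genes)
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-8)
    stop("precision matrix not positive definite at strength ", strength,
         "; lower the strength (needs strength < 1/lambda_max of the ",
         "adjacency, here < ", signif(1 / max(eigen(A, symmetric = TRUE,
         only.values = TRUE)$values), 4), ")")
  pcorTrue <- strength * A
  storage.mode(edges) <- "character"
  new("GroundTruthModel", genes = genes, omega = omega,
      pcorTrue = pcorTrue, edges = edges)
}

#' Sample a multivariate-normal expression cohort from a ground-truth model
#'
#' Draws `nSamples` observations with covariance `solve(Omega)`. An optional
#' positive shift mimics a log-CPM location; it is off by default since the
#' method consumes already-normalized log expression and is
#' location-invariant.
#'
#' @param model a [GroundTruthModel-class].
#' @param nSamples number of samples (>= 2).
#' @param seed RNG seed.
#' @param population optional single label recorded for every sample.
#' @param shift scalar added to all values (default 0).
#' @return a `SummarizedExperiment` (genes x samples).
#' @export
sampleCohort <- function(model, nSamples, seed = NULL, population = NULL,
                         shift = 0) {
  if (nSamples < 2) stop("nSamples must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  sigma <- solve(model@omega)
  X <- MASS::mvrnorm(nSamples, mu = rep(shift, length(model@genes)),
                     Sigma = sigma)
  colnames(X) <- model@genes
  rownames(X) <- paste0("s", seq_len(nSamples))
  pop <- if (is.null(population)) NULL else rep(population, nSamples)
  pcorExperiment(X, population = pop)
}

#' Two labeled cohorts with known differential edges
#'
#' Samples a cohort from each model, concatenates them with population
#' labels `"A"`/`"B"`, and records the edges whose implied partial
#' correlations differ by more than `margin`.
#'
#' @param modelA,modelB [GroundTruthModel-class] objects on the same genes.
#' @param nA,nB samples per population.
#' @param seed RNG seed.
#' @param margin minimum implied-pcor difference defining a true
#'   differential edge.
#' @return list with `experiment` (labeled `SummarizedExperiment`) and
#'   `truthDiff` (two-column matrix of differential gene pairs).
#' @export
makeDifferentialPair <- function(modelA, modelB, nA, nB, seed = NULL,
                                 margin = 0.1) {
  if (!identical(modelA@genes, modelB@genes))
    stop("models must share the same gene list")
  if (!is.null(seed)) set.seed(seed)
  XA <- t(assay(sampleCohort(modelA, nA)))
  XB <- t(assay(sampleCohort(modelB, nB)))
  se <- pcorExperiment(rbind(XA, XB),
                       population = rep(c("A", "B"), c(nA, nB)))
  dp <- abs(modelA@pcorTrue - modelB@pcorTrue)
  ij <- which(upper.tri(dp) & dp > margin, arr.ind = TRUE)
  truth <- cbind(modelA@genes[ij[, 1]], modelA@genes[ij[, 2]])
  list(experiment = se, truthDiff = truth)
}

#' Prior graph partially concordant with the true structure
#'
#' Keeps a `concordance` fraction of the model's true direct edges and adds
#' `extraEdges` random non-true edges, emulating an interaction network
#' that is informative but imperfect.
#'
#' @param model a [GroundTruthModel-class].
#' @param concordance fraction of true edges retained, in `[0, 1]`.
#' @param extraEdges count of spurious edges added.
#' @param seed RNG seed.
#' @return an `igraph` prior graph over the model's genes.
#' @export
makePrior <- function(model, concordance = 1, extraEdges = 0, seed = NULL) {
  if (concordance < 0 || concordance > 1) stop("concordance must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  genes <- model@genes
  tr <- model@edges
  nKeep <- round(concordance * nrow(tr))
  keep <- if (nKeep > 0) tr[sample.int(nrow(tr), nKeep), , drop = FALSE]
          else tr[0, , drop = FALSE]
  trueKey <- paste(pmin(tr[, 1], tr[, 2]), pmax(tr[, 1], tr[, 2]))
  extra <- matrix(character(0), 0, 2)
  if (extraEdges > 0) {
    pt_ <- .pairTable(genes)
    allKey <- paste(pmin(pt_$geneA, pt_$geneB), pmax(pt_$geneA, pt_$geneB))
    cand <- which(!(allKey %in% trueKey))
    if (length(cand) < extraEdges) stop("not enough non-true pairs available")
    pick <- sample(cand, extraEdges)
    extra <- cbind(pt_$geneA[pick], pt_$geneB[pick])
  }
  el <- rbind(keep, extra)
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(genes)
  if (nrow(el)) g <- igraph::add_edges(g, rbind(el[, 1], el[, 2]))
  igraph::simplify(g)
}
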