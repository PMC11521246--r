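#' @import methods
#' @importFrom stats cor sd quantile pt ppois p.adjust runif rnorm hclust cutree as.dist setNames complete.cases
#' @importFrom utils read.table write.table combn head
NULL

#' Personalized PageRank prior scores for an analysis gene universe
#'
#' Holds, for every gene in the analysis universe, its single-seed
#' personalized PageRank vector over the universe, computed on a
#' protein-protein interaction (or other biological) prior graph.
#' The pair-specific regularization vector for genes \eqn{(i, j)} is the
#' elementwise reciprocal of the average of rows \eqn{i} and \eqn{j}
#' (restart mass split equally over the two seeds; for graphs without
#' dangling nodes this equals a single run restarted uniformly on
#' \eqn{\{i, j\}}, by linearity of PageRank in the restart distribution).
#'
#' @slot scores numeric matrix, genes x genes; `scores[g, k]` is the
#'   PageRank score of gene `k` under restart to gene `g`, restricted to the
#'   analysis universe. Rows of genes absent from the prior graph are zero.
#' @slot genes character vector of the analysis gene universe (row/col order).
#' @slot inGraph logical vector: is each universe gene a node of the prior.
#' @slot damping PageRank damping factor used.
#' @export
setClass("PriorScores",
  representation(
    scores  = "matrix",
    genes   = "character",
    inGraph = "logical",
    damping = "numeric"
  )
)

setValidity("PriorScores", function(object) {
  s <- object@scores
  g <- object@genes
  msg <- character()
  if (nrow(s) != length(g) || ncol(s) != length(g))
    msg <- c(msg, "scores must be a square genes x genes matrix")
  if (!identical(rownames(s), g) || !identical(colnames(s), g))
    msg <- c(msg, "dimnames of scores must equal genes")
  if (anyDuplicated(g)) msg <- c(msg, "gene ids must be unique")
  if (length(object@inGraph) != length(g))
    msg <- c(msg, "inGraph must have one entry per gene")
  if (any(s < 0)) msg <- c(msg, "PageRank scores must be non-negative")
  if (length(object@damping) != 1L || object@damping <= 0 || object@damping >= 1)
    msg <- c(msg, "damping must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Ridge partial-correlation matrix for one parameter setting
#'
#' Symmetric gene x gene matrix of gene-specific ridge partial correlations
#' computed at one `(nGenes, minLambda)` setting, plus zero-variance flags.
#'
#' @slot pcor symmetric numeric matrix of partial correlations; diagonal 1.
#' @slot nGenes number of controlling genes used.
#' @slot minLambda minimum of the normalized regularization vector.
#' @slot flagged logical matrix marking pairs where a residual had zero
#'   variance (value forced to 0).
#' @export
setClass("PCorResult",
  representation(
    pcor      = "matrix",
    nGenes    = "integer",
    minLambda = "numeric",
    flagged   = "matrix"
  )
)

setValidity("PCorResult", function(object) {
  p <- object@pcor
  msg <- character()
  if (nrow(p) != ncol(p)) msg <- c(msg, "pcor must be square")
  if (max(abs(p - t(p))) > 1e-12) msg <- c(msg, "pcor must be symmetric (1e-12)")
  if (any(p < -1 - 1e-8 | p > 1 + 1e-8)) msg <- c(msg, "pcor values must lie in [-1, 1]")
  if (!identical(dim(object@flagged), dim(p))) msg <- c(msg, "flagged must match pcor dims")
  if (length(msg)) msg else TRUE
})

#' Gaussian graphical model ground truth for synthetic cohorts
#'
#' A sparse, positive-definite, unit-diagonal precision matrix together with
#' the partial correlations it implies and the list of direct (conditional)
#' dependencies, used to generate expression cohorts with known structure.
#'
#' @slot genes character gene ids.
#' @slot omega precision matrix (symmetric positive definite, unit diagonal).
#' @slot pcorTrue implied partial correlations \eqn{-\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}}.
#' @slot edges two-column character matrix of direct-dependency gene pairs.
#' @export
setClass("GroundTruthModel",
  representation(
    genes    = "character",
    omega    = "matrix",
    pcorTrue = "matrix",
    edges    = "matrix"
  )
)

setValidity("GroundTruthModel", function(object) {
  o <- object@omega
  msg <- character()
  if (nrow(o) != length(object@genes)) msg <- c(msg, "omega dim must match genes")
  if (max(abs(o - t(o))) > 1e-10) msg <- c(msg, "omega must be symmetric")
  ev <- tryCatch(min(eigen(o, symmetric = TRUE, only.values = TRUE)$values),
                 error = function(e) NA_real_)
  if (!is.na(ev) && ev <= 0) msg <- c(msg, "omega must be positive definite")
  pt <- object@pcorTrue
  if (any(abs(pt[upper.tri(pt)]) >= 1)) msg <- c(msg, "implied pcor must be in (-1, 1)")
  if (length(msg)) msg else TRUE
})
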