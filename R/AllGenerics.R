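#' Accessors for RidgePcor classes
#'
#' `pcorValues()` returns the symmetric partial-correlation matrix of a
#' [PCorResult-class]; `pcorParams()` its `(nGenes, minLambda)` setting;
#' `priorGenes()` the gene universe of a [PriorScores-class];
#' `pagerankMatrix()` its genes x genes single-seed PageRank score matrix;
#' `truePcor()` and `trueEdges()` the implied partial correlations and
#' direct-edge list of a [GroundTruthModel-class].
#'
#' @param object a RidgePcor S4 object.
#' @return see individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pcorValues", function(object) standardGeneric("pcorValues"))

#' @rdname accessors
#' @export
setGeneric("pcorParams", function(object) standardGeneric("pcorParams"))

#' @rdname accessors
#' @export
setGeneric("priorGenes", function(object) standardGeneric("priorGenes"))

#' @rdname accessors
#' @export
setGeneric("pagerankMatrix", function(object) standardGeneric("pagerankMatrix"))

#' @rdname accessors
#' @export
setGeneric("truePcor", function(object) standardGeneric("truePcor"))

#' @rdname accessors
#' @export
setGeneric("trueEdges", function(object) standardGeneric("trueEdges"))

#' @rdname accessors
#' @export
setMethod("pcorValues", "PCorResult", function(object) object@pcor)

#' @rdname accessors
#' @export
setMethod("pcorParams", "PCorResult", function(object)
  list(nGenes = object@nGenes, minLambda = object@minLambda))

#' @rdname accessors
#' @export
setMethod("priorGenes", "PriorScores", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("pagerankMatrix", "PriorScores", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("truePcor", "GroundTruthModel", function(object) object@pcorTrue)

#' @rdname accessors
#' @export
setMethod("trueEdges", "GroundTruthModel", function(object) object@edges)

setMethod("show", "PriorScores", function(object) {
  cat("PriorScores over", length(object@genes), "genes (",
      sum(object@inGraph), "in prior graph ), damping =", object@damping, "\n")
})

setMethod("show", "PCorResult", function(object) {
  p <- object@pcor
  off <- p[upper.tri(p)]
  cat(sprintf(
    "PCorResult: %d genes, nGenes = %d, minLambda = %g\n  |pcor| median %.4f, max %.4f, flagged pairs %d\n",
    nrow(p), object@nGenes, object@minLambda,
    stats::median(abs(off)), max(abs(off)), sum(object@flagged[upper.tri(p)])))
})

setMethod("show", "GroundTruthModel", function(object) {
  cat(sprintf("GroundTruthModel: %d genes, %d direct edges, min eigenvalue %.4f\n",
              length(object@genes), nrow(object@edges),
              min(eigen(object@omega, symmetric = TRUE, only.values = TRUE)$values)))
})
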