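#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Build an expression container with population labels
#'
#' Wraps a numeric expression matrix and a binary population label per
#' sample into a [SummarizedExperiment::SummarizedExperiment] (genes as
#' rows, samples as columns, labels in `colData(x)$population`), the
#' container accepted by all network functions.
#'
#' @param values numeric matrix; samples x genes by default.
#' @param population vector of per-sample population labels (2 levels for
#'   differential analyses), or `NULL`.
#' @param genesAsRows set `TRUE` if `values` is already genes x samples.
#' @return a `SummarizedExperiment`.
#' @export
pcorExperiment <- function(values, population = NULL, genesAsRows = FALSE) {
  values <- as.matrix(values)
  if (!genesAsRows) values <- t(values)
  if (anyNA(values)) stop("expression matrix must not contain missing values")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  cd <- if (is.null(population)) S4Vectors::DataFrame(row.names = colnames(values))
        else {
          if (length(population) != ncol(values))
            stop("population must have one label per sample")
          S4Vectors::DataFrame(population = as.character(population),
                               row.names = colnames(values))
        }
  SummarizedExperiment(assays = list(expr = values), colData = cd)
}

# samples x genes numeric matrix from an SE or a plain matrix
.exprMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) return(t(assay(x)))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  x
}

.populationOf <- function(x) {
  if (!is(x, "SummarizedExperiment")) return(NULL)
  cd <- colData(x)
  if ("population" %in% colnames(cd)) as.character(cd$population) else NULL
}

# center and unit-scale columns; zero-variance columns stay zero (flagged)
.standardize <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  s <- sqrt(colSums(X^2) / pmax(nrow(X) - 1, 1))
  zero <- s <= 0
  s[zero] <- 1
  list(X = sweep(X, 2, s, "/"), zeroVar = zero)
}

#' Generalized ridge regression residuals for one target gene
#'
#' Solves \eqn{\hat\beta = \arg\min_\beta \|y - Z\beta\|^2 + \|\lambda \cdot \beta\|^2}
#' (elementwise penalty product) in closed form,
#' \eqn{\hat\beta = (Z^\top Z + \mathrm{diag}(\lambda^2))^{-1} Z^\top y},
#' and returns coefficients and residuals. Inputs are centered internally.
#' With `penalty = "standard"` the classical generalized-ridge form
#' \eqn{(Z^\top Z + \mathrm{diag}(\lambda))^{-1}} is used instead.
#'
#' @param y numeric response vector (one gene's expression).
#' @param controls numeric matrix of controlling-gene columns (may have 0
#'   columns).
#' @param lam non-negative penalty per control column.
#' @param penalty `"squared"` (penalty matrix `diag(lam^2)`, the literal
#'   reading of the squared elementwise-product norm) or `"standard"`
#'   (`diag(lam)`).
#' @return list with `coefficients`, `residuals`, `fitted`.
#' @export
ridgeResidual <- function(y, controls, lam = numeric(0),
                          penalty = c("squared", "standard")) {
  penalty <- match.arg(penalty)
  y <- as.numeric(y)
  yc <- y - mean(y)
  if (is.null(controls) || NCOL(controls) == 0L)
    return(list(coefficients = numeric(0), residuals = yc,
                fitted = rep(0, length(yc))))
  Z <- as.matrix(controls)
  if (nrow(Z) != length(y)) stop("controls and y must have equal length")
  if (length(lam) != ncol(Z)) stop("lam must have one entry per control")
  if (any(lam < 0) || any(!is.finite(lam))) stop("lam must be finite and >= 0")
  Zc <- sweep(Z, 2, colMeans(Z))
  pen <- if (penalty == "squared") lam^2 else lam
  A <- crossprod(Zc) + diag(pen, ncol(Zc))
  b <- crossprod(Zc, yc)
  beta <- tryCatch(solve(A, b), error = function(e) {
    warning("singular ridge system; using pseudo-inverse")
    MASS::ginv(A) %*% b
  })
  fit <- drop(Zc %*% beta)
  list(coefficients = drop(beta), residuals = yc - fit, fitted = fit)
}

# per-pair controlling sets and penalties, fixed by (prior, params) only.
# Pairs range over `genes`; controls may come from the whole `universe`
# (all genes of the expression matrix), mirroring a regional pair analysis
# with transcriptome-wide controlling genes.
# Returns list of (i, j = pair col indices, ci = control col indices,
# pen = penalty values), indices into the universe.
.pairPlan <- function(prior, genes, nGenes, minLambda, universe = genes) {
  p <- length(genes)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  plan <- vector("list", nrow(pairs))
  idx <- stats::setNames(seq_along(universe), universe)
  gi <- unname(idx[genes])
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (nGenes == 0) {
      plan[[r]] <- list(i = gi[i], j = gi[j], ci = integer(0), pen = numeric(0))
      next
    }
    lam <- regularizationVector(prior, genes[i], genes[j])
    lam <- lam[names(lam) %in% universe]
    sel <- suppressWarnings(normalizeRegularization(lam, minLambda, nGenes))
    plan[[r]] <- list(i = gi[i], j = gi[j], ci = unname(idx[names(sel)]),
                      pen = unname(sel))
  }
  plan
}

# pcor for every planned pair from the cross-product matrix S of the
# standardized data; covIdx are unpenalized columns appended to every model.
.pcorFromCross <- function(S, plan, p, covIdx = integer(0), penalty = "squared",
                           zeroVar = NULL) {
  out <- diag(1, p)
  flags <- matrix(FALSE, p, p)
  for (z in plan) {
    i <- z$i; j <- z$j
    if (!is.null(zeroVar) && (zeroVar[i] || zeroVar[j])) {
      out[i, j] <- out[j, i] <- 0
      flags[i, j] <- flags[j, i] <- TRUE
      next
    }
    C <- c(z$ci, covIdx)
    if (length(C) == 0L) {
      v <- S[i, j] / sqrt(S[i, i] * S[j, j])
    } else {
      pen <- c(if (penalty == "squared") z$pen^2 else z$pen,
               rep(0, length(covIdx)))
      A <- S[C, C, drop = FALSE] + diag(pen, length(C))
      bi <- S[C, i]; bj <- S[C, j]
      bb <- tryCatch(solve(A, cbind(bi, bj)), error = function(e)
        MASS::ginv(A) %*% cbind(bi, bj))
      betaI <- bb[, 1]; betaJ <- bb[, 2]
      Scc <- S[C, C, drop = FALSE]
      q <- drop(crossprod(betaI, Scc %*% betaJ))
      qi <- drop(crossprod(betaI, Scc %*% betaI))
      qj <- drop(crossprod(betaJ, Scc %*% betaJ))
      varI <- S[i, i] - 2 * sum(bi * betaI) + qi
      varJ <- S[j, j] - 2 * sum(bj * betaJ) + qj
      covIJ <- S[i, j] - sum(bj * betaI) - sum(bi * betaJ) + q
      if (varI <= 1e-12 || varJ <= 1e-12) {
        out[i, j] <- out[j, i] <- 0
        flags[i, j] <- flags[j, i] <- TRUE
        next
      }
      v <- covIJ / sqrt(varI * varJ)
    }
    v <- max(-1, min(1, v))
    out[i, j] <- out[j, i] <- v
  }
  list(pcor = out, flagged = flags)
}

# full pipeline on a raw samples x genes matrix given a precomputed plan
.pcorWithPlan <- function(X, plan, covariates = NULL, penalty = "squared") {
  p <- ncol(X)
  std <- .standardize(X)
  Xs <- std$X
  covIdx <- integer(0)
  if (!is.null(covariates)) {
    W <- as.matrix(covariates)
    if (nrow(W) != nrow(X)) stop("covariates must have one row per sample")
    W <- sweep(W, 2, colMeans(W))
    covIdx <- ncol(Xs) + seq_len(ncol(W))
    Xs <- cbind(Xs, W)
  }
  S <- crossprod(Xs)
  r <- .pcorFromCross(S, plan, p, covIdx, penalty, zeroVar = std$zeroVar)
  dimnames(r$pcor) <- dimnames(r$flagged) <- list(colnames(X), colnames(X))
  r
}

#' Gene-specific ridge partial correlation for one gene pair
#'
#' Residualizes each gene of the pair on the same set of controlling genes
#' -- the `nGenes` genes with highest prior relatedness (smallest penalty)
#' to the pair -- under a generalized ridge penalty normalized to minimum
#' `minLambda`, and returns the Pearson correlation of the two residual
#' vectors. `nGenes = 0` reduces to the marginal Pearson correlation;
#' `minLambda = 0` with all other genes as controls is the canonical
#' partial correlation.
#'
#' @param x expression data: `SummarizedExperiment` (genes x samples) or
#'   numeric matrix (samples x genes).
#' @param geneI,geneJ gene ids of the pair.
#' @param prior a [PriorScores-class] over (at least) the genes of `x`.
#' @param nGenes number of controlling genes.
#' @param minLambda minimum of the normalized penalty vector.
#' @param covariates optional samples x k numeric matrix entering every
#'   regression unpenalized.
#' @param penalty see [ridgeResidual()].
#' @return a single partial-correlation value in `[-1, 1]`.
#' @export
pcorPair <- function(x, geneI, geneJ, prior, nGenes, minLambda,
                     covariates = NULL, penalty = c("squared", "standard")) {
  penalty <- match.arg(penalty)
  X <- .exprMatrix(x)
  if (geneI == geneJ) stop("geneI and geneJ must differ")
  if (!all(c(geneI, geneJ) %in% colnames(X))) stop("gene pair must be in x")
  res <- pcorMatrix(X, genes = c(geneI, geneJ), prior = prior,
                    nGenes = nGenes, minLambda = minLambda,
                    covariates = covariates, penalty = penalty)
  pcorValues(res)[geneI, geneJ]
}

#' Ridge partial-correlation matrix for one parameter setting
#'
#' Computes the symmetric matrix of gene-specific ridge partial correlations
#' over all unordered gene pairs of `genes`. Each pair uses its own
#' controlling set and penalties derived from the prior graph; both
#' regressions of a pair share them, which guarantees exact symmetry.
#' With fewer than 3 samples an error is raised.
#'
#' @inheritParams pcorPair
#' @param genes character vector of genes whose pairs are analysed
#'   (default: all in `x`). Controlling genes are still selected from every
#'   gene of `x`, mirroring a regional pair analysis with
#'   transcriptome-wide controls.
#' @return a [PCorResult-class].
#' @export
pcorMatrix <- function(x, genes = NULL, prior, nGenes, minLambda,
                       covariates = NULL, penalty = c("squared", "standard")) {
  penalty <- match.arg(penalty)
  X <- .exprMatrix(x)
  if (nrow(X) < 3) stop("at least 3 samples are required")
  if (is.null(genes)) genes <- colnames(X)
  if (!all(genes %in% colnames(X))) stop("genes must be columns of x")
  universe <- colnames(X)
  plan <- .pairPlan(prior, genes, nGenes, minLambda, universe = universe)
  r <- .pcorWithPlan(X, plan, covariates, penalty)
  dimnames(r$pcor) <- list(universe, universe)
  dimnames(r$flagged) <- list(universe, universe)
  pc <- r$pcor[genes, genes, drop = FALSE]
  fl <- r$flagged[genes, genes, drop = FALSE]
  new("PCorResult", pcor = pc, nGenes = as.integer(nGenes),
      minLambda = as.numeric(minLambda), flagged = fl)
}

#' Parameter grid for the partial-correlation analysis
#'
#' Cartesian product of the controlling-gene counts and penalty magnitudes,
#' with all `nGenes = 0` rows collapsed to a single entry (at zero
#' controlling genes the result is the marginal correlation whatever the
#' penalty). The study defaults `nGenes in {0,1,5,10,25,50,75,100}` x
#' `minLambda in {0,0.1,1,10}` give 29 settings.
#'
#' @param nGenesList integer vector of controlling-gene counts.
#' @param minLambdaList numeric vector of minimum penalties.
#' @return data.frame with columns `nGenes`, `minLambda`.
#' @export
enumerateGrid <- function(nGenesList = c(0, 1, 5, 10, 25, 50, 75, 100),
                          minLambdaList = c(0, 0.1, 1, 10)) {
  if (!length(nGenesList) || !length(minLambdaList)) stop("lists must be non-empty")
  if (any(nGenesList < 0) || any(minLambdaList < 0)) stop("grid values must be >= 0")
  g <- expand.grid(minLambda = minLambdaList, nGenes = nGenesList)[, 2:1]
  if (any(g$nGenes == 0)) {
    g <- rbind(data.frame(nGenes = 0, minLambda = 0), g[g$nGenes > 0, ])
  }
  rownames(g) <- NULL
  g
}

#' Partial-correlation matrices over a parameter grid
#'
#' @inheritParams pcorMatrix
#' @param grid data.frame as from [enumerateGrid()].
#' @return named list of [PCorResult-class] objects (`"nGenes=..,minLambda=.."`).
#' @export
pcorGrid <- function(x, prior, grid = enumerateGrid(), genes = NULL,
                     covariates = NULL, penalty = c("squared", "standard")) {
  penalty <- match.arg(penalty)
  out <- vector("list", nrow(grid))
  names(out) <- sprintf("nGenes=%g,minLambda=%g", grid$nGenes, grid$minLambda)
  for (r in seq_len(nrow(grid)))
    out[[r]] <- pcorMatrix(x, genes, prior, grid$nGenes[r], grid$minLambda[r],
                           covariates, penalty)
  out
}
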