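#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wrapper over
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of BH-adjusted q-values.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# long-format pair index for a gene set
.pairTable <- function(genes) {
  p <- length(genes)
  ij <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  data.frame(geneA = genes[ij[, 1]], geneB = genes[ij[, 2]],
             i = ij[, 1], j = ij[, 2], stringsAsFactors = FALSE)
}

.offdiag <- function(M, pt) {
  if (!is.null(rownames(M)))
    M[cbind(match(pt$geneA, rownames(M)), match(pt$geneB, colnames(M)))]
  else M[cbind(pt$i, pt$j)]
}

#' Bootstrap significance test for network edges in one population
#'
#' For one population and one `(nGenes, minLambda)` setting, resamples
#' individuals with replacement `nBoot` times and recomputes the partial
#' correlation of every gene pair. Each edge's bootstrap distribution is
#' tested one-sidedly against a pooled percentile threshold of the observed
#' partial correlations over all edges (by default the 95th percentile for
#' positive observed values, the 5th for negative), rather than against 0,
#' to retain only strong co-regulatory signals. P-values are BH-adjusted.
#'
#' @param x one-population expression data (`SummarizedExperiment` or
#'   samples x genes matrix).
#' @param prior a [PriorScores-class].
#' @param nGenes,minLambda partial-correlation parameters.
#' @param nBoot number of bootstrap resamples (study default 1000).
#' @param fdr BH false-discovery-rate threshold for the significance flag
#'   (study default 0.01).
#' @param percentiles lower/upper pooled percentiles defining the negative
#'   and positive thresholds (default `c(5, 95)`).
#' @param seed integer RNG seed.
#' @param method `"tboot"` (default): t statistic `(mean(boot) - tau)/sd(boot)`
#'   with `df = nBoot - 1`, treating the bootstrap spread as the standard
#'   error of the estimate; `"tmean"`: classical one-sample mean test with
#'   denominator `sd(boot)/sqrt(nBoot)`.
#' @param covariates,penalty passed to the partial-correlation engine.
#' @param genes optional subset of genes whose pairs are tested; controlling
#'   genes are still drawn from every gene of `x`.
#' @return data.frame with one row per unordered gene pair: observed pcor,
#'   threshold used, t statistic, p, BH q, significance flag.
#' @export
significantEdges <- function(x, prior, nGenes, minLambda, nBoot = 1000,
                             fdr = 0.01, percentiles = c(5, 95), seed = NULL,
                             method = c("tboot", "tmean"),
                             covariates = NULL,
                             penalty = c("squared", "standard"),
                             genes = NULL) {
  method <- match.arg(method)
  penalty <- match.arg(penalty)
  if (nBoot < 2) stop("nBoot must be >= 2")
  if (any(percentiles <= 0) || any(percentiles >= 100))
    stop("percentiles must be in (0, 100)")
  X <- .exprMatrix(x)
  if (nrow(X) < 10) stop("population must have >= 10 samples")
  if (is.null(genes)) genes <- colnames(X)
  if (!is.null(seed)) set.seed(seed)
  plan <- .pairPlan(prior, genes, nGenes, minLambda, universe = colnames(X))
  pt_ <- .pairTable(genes)
  obs <- .pcorWithPlan(X, plan, covariates, penalty)
  obsV <- .offdiag(obs$pcor, pt_)
  tauNeg <- unname(stats::quantile(obsV, percentiles[1] / 100))
  tauPos <- unname(stats::quantile(obsV, percentiles[2] / 100))
  B <- matrix(NA_real_, nBoot, nrow(pt_))
  for (b in seq_len(nBoot)) {
    rows <- sample.int(nrow(X), nrow(X), replace = TRUE)
    W <- if (is.null(covariates)) NULL else covariates[rows, , drop = FALSE]
    B[b, ] <- .offdiag(.pcorWithPlan(X[rows, , drop = FALSE], plan, W,
                                     penalty)$pcor, pt_)
  }
  m <- colMeans(B)
  s <- apply(B, 2, stats::sd)
  denom <- if (method == "tboot") s else s / sqrt(nBoot)
  tau <- ifelse(obsV >= 0, tauPos, tauNeg)
  tstat <- (m - tau) / denom
  pv <- ifelse(obsV >= 0,
               stats::pt(tstat, df = nBoot - 1, lower.tail = FALSE),
               stats::pt(tstat, df = nBoot - 1, lower.tail = TRUE))
  degenerate <- s <= 0
  pv[degenerate] <- 1
  tstat[degenerate] <- 0
  q <- bhAdjust(pv)
  data.frame(geneA = pt_$geneA, geneB = pt_$geneB,
             nGenes = nGenes, minLambda = minLambda,
             pcor = obsV, threshold = tau, statistic = tstat,
             p = pv, q = q, significant = q <= fdr,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

# split a labeled experiment into its two population matrices
.splitPopulations <- function(x) {
  pop <- .populationOf(x)
  if (is.null(pop)) stop("x must carry a 'population' colData column")
  lev <- unique(pop)
  if (length(lev) != 2) stop("exactly two populations are required")
  X <- .exprMatrix(x)
  list(a = X[pop == lev[1], , drop = FALSE],
       b = X[pop == lev[2], , drop = FALSE],
       levels = lev)
}

#' Permutation test for differential edges between two populations
#'
#' Tests, per gene pair, whether the partial correlation differs between
#' two populations (e.g. cases vs controls). The observed statistic is
#' `delta = pcorA - pcorB`; its null distribution is built by shuffling the
#' population labels (`nPerm` times, preserving group sizes) and recomputing
#' the difference. By default each edge is tested against its own null with
#' a t-style statistic `(delta_obs - mean_null)/sd_null` (df `nPerm - 1`);
#' `method = "empirical"` returns the add-one two-sided permutation p-value
#' instead. P-values are BH-adjusted, FDR 0.1 by default.
#'
#' @param xA two-population labeled `SummarizedExperiment`, or population A
#'   data (matrix/SE) when `xB` is given.
#' @param xB population B data, or `NULL` when `xA` carries labels.
#' @param prior a [PriorScores-class].
#' @param nGenes,minLambda partial-correlation parameters.
#' @param nPerm number of label permutations (study default 1000).
#' @param fdr BH threshold for the significance flag (study default 0.1).
#' @param seed integer RNG seed.
#' @param method `"t"` (default) or `"empirical"`.
#' @param covariates,penalty passed to the partial-correlation engine
#'   (covariate rows must align with `rbind(A, B)`).
#' @param genes optional subset of genes whose pairs are tested; controlling
#'   genes are still drawn from every gene of the data.
#' @return data.frame per unordered gene pair: pcor in each population,
#'   delta, statistic, p, BH q, significance flag.
#' @export
differentialEdges <- function(xA, xB = NULL, prior, nGenes, minLambda,
                              nPerm = 1000, fdr = 0.1, seed = NULL,
                              method = c("t", "empirical"),
                              covariates = NULL,
                              penalty = c("squared", "standard"),
                              genes = NULL) {
  method <- match.arg(method)
  penalty <- match.arg(penalty)
  if (nPerm < 2) stop("nPerm must be >= 2")
  if (is.null(xB)) {
    sp <- .splitPopulations(xA)
    A <- sp$a; Bm <- sp$b
  } else {
    A <- .exprMatrix(xA); Bm <- .exprMatrix(xB)
  }
  if (nrow(A) < 10 || nrow(Bm) < 10) stop("both populations need >= 10 samples")
  if (!identical(colnames(A), colnames(Bm))) stop("gene sets must match")
  if (is.null(genes)) genes <- colnames(A)
  if (!is.null(seed)) set.seed(seed)
  plan <- .pairPlan(prior, genes, nGenes, minLambda, universe = colnames(A))
  pt_ <- .pairTable(genes)
  nA <- nrow(A)
  pooled <- rbind(A, Bm)
  pcorA <- .offdiag(.pcorWithPlan(A, plan,
    if (is.null(covariates)) NULL else covariates[seq_len(nA), , drop = FALSE],
    penalty)$pcor, pt_)
  pcorB <- .offdiag(.pcorWithPlan(Bm, plan,
    if (is.null(covariates)) NULL else covariates[-seq_len(nA), , drop = FALSE],
    penalty)$pcor, pt_)
  delta <- pcorA - pcorB
  P <- matrix(NA_real_, nPerm, nrow(pt_))
  for (b in seq_len(nPerm)) {
    pa <- sample.int(nrow(pooled), nA)
    Wa <- Wb <- NULL
    if (!is.null(covariates)) {
      Wa <- covariates[pa, , drop = FALSE]
      Wb <- covariates[-pa, , drop = FALSE]
    }
    P[b, ] <- .offdiag(.pcorWithPlan(pooled[pa, , drop = FALSE], plan, Wa,
                                     penalty)$pcor, pt_) -
              .offdiag(.pcorWithPlan(pooled[-pa, , drop = FALSE], plan, Wb,
                                     penalty)$pcor, pt_)
  }
  mu <- colMeans(P)
  s <- apply(P, 2, stats::sd)
  if (method == "t") {
    z <- (delta - mu) / s
    pv <- 2 * stats::pt(-abs(z), df = nPerm - 1)
    degenerate <- s <= 0
    pv[degenerate] <- 1
    z[degenerate] <- 0
  } else {
    z <- (delta - mu) / ifelse(s > 0, s, 1)
    pv <- (1 + colSums(abs(P) >= matrix(abs(delta), nPerm, length(delta),
                                        byrow = TRUE))) / (nPerm + 1)
    degenerate <- rep(FALSE, length(delta))
  }
  q <- bhAdjust(pmin(pv, 1))
  data.frame(geneA = pt_$geneA, geneB = pt_$geneB,
             nGenes = nGenes, minLambda = minLambda,
             pcorA = pcorA, pcorB = pcorB, delta = delta,
             statistic = z, p = pmin(pv, 1), q = q, significant = q <= fdr,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Consensus of differential edges across parameter settings
#'
#' Restricts a list of per-setting differential edge tables to settings with
#' at least `minNGenes` controlling genes, then returns the union of their
#' significant edges with, per edge, the number of qualifying settings in
#' which it was significant (frequency) and its mean delta across all
#' qualifying settings.
#'
#' @param tables list of data.frames as returned by [differentialEdges()].
#' @param minNGenes minimum `nGenes` for a setting to qualify (study
#'   default 5).
#' @return data.frame with columns `geneA`, `geneB`, `frequency`,
#'   `meanDelta`, sorted by decreasing frequency.
#' @export
consensusDifferentialEdges <- function(tables, minNGenes = 5) {
  if (length(tables) == 0)
    return(data.frame(geneA = character(), geneB = character(),
                      frequency = integer(), meanDelta = numeric()))
  keep <- vapply(tables, function(t) t$nGenes[1] >= minNGenes, TRUE)
  tables <- tables[keep]
  if (length(tables) == 0)
    return(data.frame(geneA = character(), geneB = character(),
                      frequency = integer(), meanDelta = numeric()))
  key <- function(t) paste(pmin(t$geneA, t$geneB), pmax(t$geneA, t$geneB),
                           sep = "\r")
  sigKeys <- unlist(lapply(tables, function(t) key(t)[t$significant]))
  if (length(sigKeys) == 0)
    return(data.frame(geneA = character(), geneB = character(),
                      frequency = integer(), meanDelta = numeric()))
  freq <- table(sigKeys)
  deltaSum <- deltaN <- stats::setNames(numeric(length(freq)), names(freq))
  for (t in tables) {
    k <- key(t)
    hit <- k %in% names(freq)
    deltaSum[k[hit]] <- deltaSum[k[hit]] + t$delta[hit]
    deltaN[k[hit]] <- deltaN[k[hit]] + 1
  }
  parts <- strsplit(names(freq), "\r", fixed = TRUE)
  out <- data.frame(geneA = vapply(parts, `[`, "", 1L),
                    geneB = vapply(parts, `[`, "", 2L),
                    frequency = as.integer(freq),
                    meanDelta = unname(deltaSum / deltaN),
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$geneA, out$geneB), , drop = FALSE]
}
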