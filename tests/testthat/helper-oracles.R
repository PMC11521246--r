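# Independent oracles used by the unit and acceptance tests. Each one is a
# deliberately naive implementation (numerical optimizer, brute-force
# enumeration, direct formula) sharing no code with the package internals.

# Generalized ridge coefficients via numerical minimization of the objective
# ||y - Z beta||^2 + sum(pen * beta^2) on centered data.
oracleRidge <- function(y, Z, pen) {
  yc <- y - mean(y)
  Zc <- sweep(Z, 2, colMeans(Z))
  obj <- function(beta) sum((yc - Zc %*% beta)^2) + sum(pen * beta^2)
  fit <- stats::optim(rep(0, ncol(Zc)), obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit$par
}

# Partial correlation matrix implied by a precision matrix.
oraclePcorFromPrecision <- function(omega) {
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * outer(d, d)
  diag(pc) <- 1
  pc
}

# Sample canonical partial correlations: invert the sample covariance.
oracleSamplePcor <- function(X) {
  oraclePcorFromPrecision(solve(stats::cov(X)))
}

# Benjamini-Hochberg step-up, written from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# All set partitions of n elements as a list of membership vectors
# (restricted growth strings).
oraclePartitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxUsed) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxUsed + 1))
      rec(c(prefix, v), max(maxUsed, v))
  }
  rec(integer(0), 0L)
  out
}

# Newman-Girvan modularity straight from the adjacency-matrix formula
# Q = (1/2m) * sum_ij [A_ij - k_i k_j / 2m] delta(c_i, c_j).
oracleModularity <- function(adj, membership) {
  m2 <- sum(adj)
  if (m2 == 0) return(0)
  deg <- rowSums(adj)
  same <- outer(membership, membership, "==")
  sum((adj - outer(deg, deg) / m2) * same) / m2
}

# Brute-force count of k-point windows: every k-subset of same-chromosome
# loci whose members are consecutive order statistics and whose span is at
# most L.
oracleCountRegions <- function(loci, k, L) {
  total <- 0L
  for (ch in unique(loci$chrom)) {
    pos <- sort(loci$pos[loci$chrom == ch])
    n <- length(pos)
    if (n < k) next
    sets <- utils::combn(n, k)
    for (cI in seq_len(ncol(sets))) {
      s <- sets[, cI]
      if (max(s) - min(s) == k - 1 && pos[max(s)] - pos[min(s)] <= L)
        total <- total + 1L
    }
  }
  total
}

# Area under the ROC curve via the rank-sum identity.
oracleAUC <- function(scores, labels) {
  r <- rank(scores)
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
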