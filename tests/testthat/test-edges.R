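test_that("bhAdjust matches p.adjust oracle and hand examples", {
  expect_equal(bhAdjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  set.seed(71)
  p <- runif(200)^2
  q <- bhAdjust(p)
  expect_equal(q, oracleBH(p), tolerance = 1e-12)
  # step-up output is monotone non-decreasing in sorted p order
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("significantEdges returns a well-formed deterministic table", {
  X <- fixtureExpression(p = 6, n = 60)
  pr <- fixtureCompletePrior(colnames(X))
  t1 <- significantEdges(X, pr, nGenes = 2, minLambda = 1, nBoot = 50,
                         seed = 7)
  t2 <- significantEdges(X, pr, nGenes = 2, minLambda = 1, nBoot = 50,
                         seed = 7)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), choose(6, 2))
  expect_true(all(c("geneA", "geneB", "pcor", "threshold", "statistic",
                    "p", "q", "significant") %in% names(t1)))
  expect_true(all(t1$p >= 0 & t1$p <= 1))
  expect_true(all(t1$q >= t1$p - 1e-12))
  expect_equal(t1$q, bhAdjust(t1$p))
  # one-sided thresholds: positive observed pcor tested against the upper
  # pooled percentile, negative against the lower
  tauPos <- unname(quantile(t1$pcor, 0.95))
  tauNeg <- unname(quantile(t1$pcor, 0.05))
  expect_true(all(t1$threshold[t1$pcor >= 0] == tauPos))
  expect_true(all(t1$threshold[t1$pcor < 0] == tauNeg))
})

test_that("significantEdges flags a strong planted edge", {
  set.seed(81)
  n <- 150
  z <- rnorm(n)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("g", sprintf("%02d", 1:10))))
  X[, 1] <- z + rnorm(n, sd = 0.4)
  X[, 2] <- z + rnorm(n, sd = 0.4)
  pr <- fixtureCompletePrior(colnames(X))
  tab <- significantEdges(X, pr, nGenes = 0, minLambda = 0, nBoot = 199,
                          fdr = 0.01, seed = 8)
  hit <- tab$geneA == "g01" & tab$geneB == "g02"
  expect_true(tab$significant[hit])
  expect_lt(mean(tab$significant[!hit]), 0.2)
})

test_that("significantEdges validates inputs", {
  X <- fixtureExpression(p = 4, n = 30)
  pr <- fixtureCompletePrior(colnames(X))
  expect_error(significantEdges(X[1:5, ], pr, 1, 0), ">= 10 samples")
  expect_error(significantEdges(X, pr, 1, 0, nBoot = 1), "nBoot")
  expect_error(significantEdges(X, pr, 1, 0, nBoot = 20,
                                percentiles = c(0, 95)), "percentiles")
})

test_that("differentialEdges detects a planted differential edge", {
  genes <- paste0("g", 1:6)
  edgeOn <- makePrecision(genes, edges = cbind("g1", "g2"), strength = 0.6)
  edgeOff <- makePrecision(genes, edges = cbind("g3", "g4"), strength = 0.3)
  dp <- makeDifferentialPair(edgeOn, edgeOff, nA = 120, nB = 120, seed = 91)
  pr <- fixtureCompletePrior(genes)
  tab <- differentialEdges(dp$experiment, prior = pr, nGenes = 4,
                           minLambda = 0, nPerm = 99, seed = 92)
  expect_equal(nrow(tab), choose(6, 2))
  hit <- tab$geneA == "g1" & tab$geneB == "g2"
  expect_true(tab$significant[hit])
  expect_gt(abs(tab$delta[hit]), 0.3)
  # the planted truth table contains both differential pairs
  keys <- paste(dp$truthDiff[, 1], dp$truthDiff[, 2])
  expect_setequal(keys, c("g1 g2", "g3 g4"))
})

test_that("differentialEdges accepts two matrices and matches the labeled path", {
  genes <- paste0("g", 1:5)
  mA <- makePrecision(genes, edges = cbind("g1", "g2"), strength = 0.5)
  mB <- makePrecision(genes, edges = matrix(character(0), 0, 2))
  A <- t(SummarizedExperiment::assay(sampleCohort(mA, 80, seed = 1)))
  B <- t(SummarizedExperiment::assay(sampleCohort(mB, 70, seed = 2)))
  se <- pcorExperiment(rbind(A, B), population = rep(c("A", "B"), c(80, 70)))
  pr <- fixtureCompletePrior(genes)
  tLab <- differentialEdges(se, prior = pr, nGenes = 3, minLambda = 0.1,
                            nPerm = 60, seed = 5)
  tMat <- differentialEdges(A, B, prior = pr, nGenes = 3, minLambda = 0.1,
                            nPerm = 60, seed = 5)
  expect_equal(tLab, tMat)
})

test_that("differentialEdges empirical method gives valid add-one p-values", {
  genes <- paste0("g", 1:4)
  m <- makePrecision(genes, edges = matrix(character(0), 0, 2))
  dp <- makeDifferentialPair(m, m, nA = 40, nB = 40, seed = 3)
  pr <- fixtureCompletePrior(genes)
  nPerm <- 49
  tab <- differentialEdges(dp$experiment, prior = pr, nGenes = 2,
                           minLambda = 1, nPerm = nPerm, seed = 6,
                           method = "empirical")
  expect_true(all(tab$p >= 1 / (nPerm + 1)))
  expect_true(all(tab$p <= 1))
})

test_that("differentialEdges validates populations", {
  X <- fixtureExpression(p = 4, n = 30)
  se <- pcorExperiment(X)
  pr <- fixtureCompletePrior(colnames(X))
  expect_error(differentialEdges(se, prior = pr, nGenes = 1, minLambda = 0),
               "population")
  se2 <- pcorExperiment(X, population = rep("A", 30))
  expect_error(differentialEdges(se2, prior = pr, nGenes = 1, minLambda = 0),
               "two populations")
  expect_error(differentialEdges(X[1:5, ], X, prior = pr, nGenes = 1,
                                 minLambda = 0), ">= 10 samples")
  Y <- X; colnames(Y) <- paste0("h", 1:4)
  expect_error(differentialEdges(X, Y, prior = pr, nGenes = 1,
                                 minLambda = 0), "gene sets")
})

test_that("consensusDifferentialEdges filters settings and aggregates", {
  mk <- function(nG, sig, delta) {
    data.frame(geneA = c("a", "a", "b"), geneB = c("b", "c", "c"),
               nGenes = nG, minLambda = 0, pcorA = 0, pcorB = 0,
               delta = delta, statistic = 0, p = 0.5, q = 0.5,
               significant = sig, degenerate = FALSE,
               stringsAsFactors = FALSE)
  }
  tabs <- list(mk(0, c(TRUE, TRUE, TRUE), c(9, 9, 9)),       # dropped (< 5)
               mk(5, c(TRUE, FALSE, FALSE), c(0.4, 0, 0)),
               mk(10, c(TRUE, TRUE, FALSE), c(0.6, 0.2, 0)))
  out <- consensusDifferentialEdges(tabs, minNGenes = 5)
  expect_equal(out$geneA, c("a", "a"))
  expect_equal(out$geneB, c("b", "c"))
  expect_equal(out$frequency, c(2L, 1L))
  # meanDelta averages over all qualifying settings, significant or not
  expect_equal(out$meanDelta, c(0.5, 0.1))
  # all settings filtered out, or nothing significant
  expect_equal(nrow(consensusDifferentialEdges(tabs[1], minNGenes = 5)), 0)
  none <- list(mk(10, c(FALSE, FALSE, FALSE), c(0, 0, 0)))
  expect_equal(nrow(consensusDifferentialEdges(none)), 0)
  expect_equal(nrow(consensusDifferentialEdges(list())), 0)
})
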