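test_that("pcorExperiment builds a labeled SummarizedExperiment", {
  X <- fixtureExpression(p = 4, n = 12)
  se <- pcorExperiment(X, population = rep(c("A", "B"), 6))
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(4L, 12L))
  expect_equal(SummarizedExperiment::assay(se), t(X))
  expect_equal(SummarizedExperiment::colData(se)$population,
               rep(c("A", "B"), 6))
  expect_error(pcorExperiment(X, population = c("A", "B")), "one label")
  X[1, 1] <- NA
  expect_error(pcorExperiment(X), "missing")
})

test_that("ridgeResidual matches a numerical-optimizer oracle", {
  set.seed(21)
  n <- 60
  Z <- matrix(rnorm(n * 4), n, 4)
  y <- Z %*% c(1, -0.5, 0, 0.3) + rnorm(n)
  lam <- c(0.5, 2, 7, 0)
  for (pen in c("squared", "standard")) {
    fit <- ridgeResidual(y, Z, lam, penalty = pen)
    penVec <- if (pen == "squared") lam^2 else lam
    expect_equal(fit$coefficients, oracleRidge(y, Z, penVec),
                 tolerance = 1e-6)
    expect_equal(fit$residuals + fit$fitted, as.numeric(y - mean(y)),
                 tolerance = 1e-12)
  }
})

test_that("ridgeResidual at zero penalty equals least squares", {
  set.seed(22)
  Z <- matrix(rnorm(50 * 3), 50, 3)
  y <- rnorm(50)
  fit <- ridgeResidual(y, Z, c(0, 0, 0))
  expect_equal(unname(fit$residuals),
               unname(stats::resid(stats::lm(y ~ Z))), tolerance = 1e-10)
  noCtl <- ridgeResidual(y, NULL)
  expect_equal(noCtl$residuals, y - mean(y))
  expect_error(ridgeResidual(y, Z, c(1, 2)), "one entry per control")
  expect_error(ridgeResidual(y, Z, c(-1, 0, 0)), "finite and >= 0")
})

test_that("pcorMatrix is exactly symmetric with unit diagonal, values in range", {
  X <- fixtureExpression(p = 8, n = 60)
  pr <- fixtureCompletePrior(colnames(X))
  res <- pcorMatrix(X, prior = pr, nGenes = 3, minLambda = 1)
  M <- pcorValues(res)
  expect_identical(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 8))
  expect_true(all(M >= -1 & M <= 1))
  expect_equal(pcorParams(res), list(nGenes = 3L, minLambda = 1))
})

test_that("nGenes = 0 reproduces the marginal Pearson correlation", {
  X <- fixtureExpression(p = 7, n = 50)
  pr <- fixtureCompletePrior(colnames(X))
  M <- pcorValues(pcorMatrix(X, prior = pr, nGenes = 0, minLambda = 5))
  expect_equal(M, stats::cor(X), tolerance = 1e-12)
})

test_that("minLambda = 0 with all controls matches the inverse-covariance oracle", {
  set.seed(33)
  X <- fixtureExpression(p = 6, n = 120, seed = 33)
  pr <- fixtureCompletePrior(colnames(X))
  M <- pcorValues(pcorMatrix(X, prior = pr, nGenes = ncol(X) - 2,
                             minLambda = 0))
  expect_equal(unname(M), unname(oracleSamplePcor(X)), tolerance = 1e-8)
})

test_that("pcorPair equals the matching pcorMatrix entry", {
  X <- fixtureExpression(p = 6, n = 40)
  pr <- fixtureCompletePrior(colnames(X))
  M <- pcorValues(pcorMatrix(X, prior = pr, nGenes = 2, minLambda = 0.5))
  v <- pcorPair(X, "g02", "g05", pr, nGenes = 2, minLambda = 0.5)
  expect_equal(v, M["g02", "g05"], tolerance = 1e-12)
  expect_error(pcorPair(X, "g02", "g02", pr, 2, 0.5), "must differ")
  expect_error(pcorPair(X, "g02", "nope", pr, 2, 0.5), "must be in x")
})

test_that("analyzing a gene subset still draws controls from the full universe", {
  set.seed(44)
  model <- makePrecision(12, density = 0.35, strength = 0.15, seed = 44)
  x <- sampleCohort(model, 150, seed = 45)
  pr <- priorScores(makePrior(model), model@genes)
  sub <- model@genes[1:4]
  full <- pcorValues(pcorMatrix(x, prior = pr, nGenes = 6, minLambda = 0.5))
  part <- pcorValues(pcorMatrix(x, genes = sub, prior = pr, nGenes = 6,
                                minLambda = 0.5))
  expect_equal(dim(part), c(4L, 4L))
  # identical values: the controlling pool for each pair is the same
  expect_equal(part, full[sub, sub], tolerance = 1e-12)
})

test_that("huge penalties push the partial back to the marginal correlation", {
  X <- fixtureExpression(p = 6, n = 80)
  pr <- fixtureCompletePrior(colnames(X))
  M <- pcorValues(pcorMatrix(X, prior = pr, nGenes = 4, minLambda = 1e8))
  expect_equal(M, stats::cor(X), tolerance = 1e-4)
})

test_that("zero-variance genes are flagged and zeroed", {
  X <- fixtureExpression(p = 5, n = 30)
  X[, 3] <- 7
  pr <- fixtureCompletePrior(colnames(X))
  res <- pcorMatrix(X, prior = pr, nGenes = 2, minLambda = 1)
  expect_true(all(res@flagged["g03", -3]))
  expect_true(all(pcorValues(res)["g03", -3] == 0))
  expect_false(any(res@flagged[-3, -3]))
})

test_that("covariates are partialled out unpenalized", {
  set.seed(55)
  n <- 400
  z <- rnorm(n)
  X <- cbind(g1 = z + rnorm(n, sd = 0.6), g2 = z + rnorm(n, sd = 0.6),
             g3 = rnorm(n), g4 = rnorm(n))
  pr <- fixtureCompletePrior(colnames(X))
  marg <- pcorPair(X, "g1", "g2", pr, nGenes = 0, minLambda = 0)
  adj <- pcorPair(X, "g1", "g2", pr, nGenes = 0, minLambda = 0,
                  covariates = cbind(z))
  expect_gt(marg, 0.5)
  expect_lt(abs(adj), 0.12)
  # unpenalized covariate equals using it as a zero-penalty control
  direct <- ridgeResidual(X[, "g1"], cbind(z), 0)$residuals
  other <- ridgeResidual(X[, "g2"], cbind(z), 0)$residuals
  expect_equal(adj, stats::cor(direct, other), tolerance = 1e-10)
})

test_that("enumerateGrid collapses nGenes = 0 and validates", {
  g <- enumerateGrid()
  expect_equal(nrow(g), 29)
  expect_equal(sum(g$nGenes == 0), 1)
  expect_equal(g[1, ], data.frame(nGenes = 0, minLambda = 0))
  g2 <- enumerateGrid(c(2, 4), c(0.5, 1, 2))
  expect_equal(nrow(g2), 6)
  expect_error(enumerateGrid(numeric(0)), "non-empty")
  expect_error(enumerateGrid(c(-1, 2)), ">= 0")
})

test_that("pcorGrid returns one named result per setting", {
  X <- fixtureExpression(p = 5, n = 40)
  pr <- fixtureCompletePrior(colnames(X))
  grid <- enumerateGrid(c(0, 2), c(0, 1))
  out <- pcorGrid(X, pr, grid)
  expect_length(out, 3)
  expect_named(out, c("nGenes=0,minLambda=0", "nGenes=2,minLambda=0",
                      "nGenes=2,minLambda=1"))
  expect_equal(pcorParams(out[[3]]), list(nGenes = 2L, minLambda = 1))
})

test_that("pcorMatrix input validation", {
  X <- fixtureExpression(p = 4, n = 30)
  pr <- fixtureCompletePrior(colnames(X))
  expect_error(pcorMatrix(X[1:2, ], prior = pr, nGenes = 1, minLambda = 0),
               "3 samples")
  expect_error(pcorMatrix(X, genes = c("g01", "zz"), prior = pr,
                          nGenes = 1, minLambda = 0), "columns of x")
})
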