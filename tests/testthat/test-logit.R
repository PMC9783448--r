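test_that("a zero functional term reduces to the baseline model", {
  grid <- quantileGrid()
  n <- 30L
  samples <- lapply(seq_len(n), function(i)
    new("FunctionSample", grid = grid, values = rep(0, 101L),
        transform = "log_density_quantile", subjectId = "x"))
  psi <- makeBasisFunctions(grid, 2L)
  basis <- new("FPCABasis", grid = grid, meanFunction = rep(0, 101L),
               eigenfunctions = psi, eigenvalues = c(1, 0.5, 0),
               nComponents = 2L, varianceFraction = 1)
  cov <- data.frame(A = rep(c(0L, 1L), n / 2), intercept = 1)
  fit <- fitDensityLogit(cov, basis, samples)
  expect_equal(fit@gamma, c(0, 0))
  lrt <- lrtVsBaseline(fit, cov)
  expect_equal(lrt$statistic, 0, tolerance = 1e-10)
  expect_equal(lrt$p, 1)
  expect_equal(lrt$df, 2L)
})

test_that("a single-component signal coefficient is recovered without bias", {
  ## oracle: simulation from a known generator; average estimate over
  ## replicates should sit near the true gamma = 1.5
  ests <- vapply(1:200, function(r) {
    st <- makeCurveStudy(400, gamma = 1.5, evals = c(1), seed = 4000 + r)
    basis <- fitFPCA(st$samples, smoothCovariance = FALSE)
    fit <- suppressWarnings(fitDensityLogit(st$cov, basis, st$samples))
    ## align sign with the generator's component
    w <- ConnDensity:::.quadWeights(basis@grid)
    s <- sign(sum(w * basis@eigenfunctions[, 1L] * st$psi[, 1L]))
    fit@gamma[1L] * s
  }, numeric(1L))
  expect_lt(abs(mean(ests) - 1.5), 0.35)
})

test_that("the study-shaped 25/22 fit returns cleanly", {
  study <- makeStudyFixture(n = 47L, nTreated = 25L, seed = 7,
                            stimulate = TRUE)
  res <- fitStudyPipeline(study)
  expect_s4_class(res$fit, "DensityLogitFit")
  expect_true(res$fit@auc >= 0 && res$fit@auc <= 1)
  expect_true(all(res$fit@fitted > 0 & res$fit@fitted < 1))
  ## bands bracket g by construction
  expect_true(all(res$fit@bandLower@values <= res$fit@g@values))
  expect_true(all(res$fit@bandUpper@values >= res$fit@g@values))
})

test_that("the fitted functional term equals direct quadrature", {
  study <- makeStudyFixture(n = 24L, nTreated = 12L, seed = 8)
  res <- fitStudyPipeline(study)
  direct <- vapply(res$densities, function(d)
    linearFunctionalScore(res$fit, d), numeric(1L))
  viaScores <- drop(res$fit@scores %*% res$fit@gamma)
  expect_lt(max(abs(direct - viaScores)), 1e-8)
  ## degenerate cases of the score integral: g == 0 gives 0 for any density
  w <- ConnDensity:::.quadWeights(quantileGrid())
  ldq1 <- applyTransform(res$densities[[1L]], "log_density_quantile")@values
  expect_identical(sum(w * 0 * ldq1), 0)
  ## g == 1 against the exact uniform density integrates to -log 2
  expect_equal(sum(w), 1)   # midpoint grid carries unit quadrature mass
  u <- applyTransform(uniformDensity(), "log_density_quantile")@values
  expect_equal(sum(w * u), -log(2), tolerance = 1e-9)
})

test_that("subject reordering leaves all estimates identical", {
  study <- makeStudyFixture(n = 20L, nTreated = 10L, seed = 9)
  res1 <- fitStudyPipeline(study)
  perm <- withr::with_seed(1, sample(20L))
  res2 <- local({
    edges <- SummarizedExperiment::assay(study, "edges")[, perm]
    dens <- lapply(seq_len(20L), function(i) fitSplineDensity(edges[, i]))
    samples <- buildFunctionalCovariates(dens, "log_density_quantile")
    basis <- fitFPCA(samples)
    cov <- as.data.frame(SummarizedExperiment::colData(study))[perm, ]
    suppressWarnings(fitDensityLogit(cov, basis, samples))
  })
  expect_equal(res1$fit@beta, res2@beta, tolerance = 1e-8)
  expect_equal(res1$fit@gamma, res2@gamma, tolerance = 1e-8)
  expect_equal(res1$fit@auc, res2@auc, tolerance = 1e-10)
})

test_that("null bands cover zero and widen as n shrinks", {
  cover <- matrix(NA_real_, 500, 2L)
  widths <- matrix(NA_real_, 500, 2L)
  for (r in 1:500) {
    for (j in 1:2) {
      n <- c(400L, 100L)[j]
      cur <- makeCurves(n, evals = c(1, 0.25), seed = 70000 + 2 * r + j)
      A <- withr::with_seed(80000 + 2 * r + j, rbinom(n, 1L, 0.5))
      cov <- data.frame(A = A, intercept = 1)
      basis <- fitFPCA(cur$samples, smoothCovariance = FALSE)
      fit <- suppressWarnings(fitDensityLogit(cov, basis, cur$samples))
      cover[r, j] <- mean(fit@bandLower@values <= 0 &
                            fit@bandUpper@values >= 0)
      widths[r, j] <- mean(fit@bandUpper@values - fit@bandLower@values)
    }
  }
  expect_gte(mean(cover[, 1L]), 0.90)
  expect_lte(mean(cover[, 1L]), 0.99)
  expect_lt(mean(widths[, 1L]), mean(widths[, 2L]))
  expect_error(coefficientBand(fit, level = 1.2), "strictly in")
})

test_that("the likelihood ratio test is calibrated on low-rank curves", {
  pvals <- vapply(1:1000, function(r) {
    n <- 150L
    cur <- makeCurves(n, evals = c(1, 0.3, 0.1), seed = 90000 + r)
    A <- withr::with_seed(95000 + r, rbinom(n, 1L, 0.5))
    cov <- data.frame(A = A, intercept = 1)
    basis <- fitFPCA(cur$samples, smoothCovariance = FALSE)
    fit <- suppressWarnings(fitDensityLogit(cov, basis, cur$samples))
    lrtVsBaseline(fit, cov)$p
  }, numeric(1L))
  rate <- mean(pvals <= 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("Bonferroni across three transforms multiplies and caps", {
  study <- makeStudyFixture(n = 20L, nTreated = 10L, seed = 10)
  res <- fitStudyPipeline(study)
  lrt <- lrtVsBaseline(res$fit, study, bonferroni = 3L)
  expect_equal(lrt$pAdjusted, min(1, lrt$p * 3))
  ## a large p caps at 1
  expect_equal(min(1, 0.9 * 3), 1)
  ## non-nested covariates rejected
  other <- makeStudyFixture(n = 20L, nTreated = 11L, seed = 11)
  expect_error(lrtVsBaseline(res$fit, other), "not nested")
})
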