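test_that("effect maps are zero when g is zero and equivariant to labels", {
  study <- makeStudyFixture(n = 16L, nTreated = 8L, p = 10L, seed = 71)
  res <- fitStudyPipeline(study)
  fit <- res$fit
  ## force a zero coefficient function
  z <- fit
  z@gamma <- rep(0, length(fit@gamma))
  z@g@values <- rep(0, length(fit@g@values))
  z@bandLower@values <- rep(0, length(fit@g@values))
  z@bandUpper@values <- rep(0, length(fit@g@values))
  M0 <- edgeEffectMap(z, res$densities[[1L]], connectivityMatrix(study, 1L))
  expect_true(all(M0 == 0))
  ## relabeling the regions permutes the effect map identically
  C <- connectivityMatrix(study, 2L)
  M <- edgeEffectMap(fit, res$densities[[2L]], C)
  perm <- withr::with_seed(72, sample(10L))
  Mp <- edgeEffectMap(fit, res$densities[[2L]], relabelRegions(C, perm))
  expect_equal(Mp, relabelRegions(M, perm), tolerance = 1e-12)
  expect_identical(M, t(M))
  expect_equal(diag(M), rep(0, 10L))
  ## transform mismatch rejected
  wrong <- fit; wrong@transform <- "identity"
  expect_error(edgeEffectMap(wrong, res$densities[[1L]], C),
               "log-density-quantile")
})

test_that("edge averages reproduce the quadrature integral at 3003 edges", {
  withr::with_seed(73, {
    p <- 78L
    prm <- vonMisesParams(1.2, 1.5)
    sub <- generateSubject(prm, p)
    es <- vectorizeUpperTriangle(sub$C)
    d <- fitSplineDensity(es)
    ## an arbitrary smooth coefficient function on the quantile grid
    grid <- quantileGrid()
    gvals <- sin(2 * pi * grid) + 0.5 * grid
    basis <- new("FPCABasis", grid = grid, meanFunction = rep(0, 101L),
                 eigenfunctions = matrix(gvals / sqrt(sum(
                   ConnDensity:::.quadWeights(grid) * gvals^2)), ncol = 1L),
                 eigenvalues = c(1), nComponents = 1L, varianceFraction = 1)
    gnorm <- sqrt(sum(ConnDensity:::.quadWeights(grid) * gvals^2))
    fit <- new("DensityLogitFit", beta = c(intercept = 0), gamma = gnorm,
               g = new("FunctionSample", grid = grid, values = gvals,
                       transform = "log_density_quantile",
                       subjectId = character(0)),
               bandLower = new("FunctionSample", grid = grid,
                               values = gvals - 1,
                               transform = "log_density_quantile",
                               subjectId = character(0)),
               bandUpper = new("FunctionSample", grid = grid,
                               values = gvals + 1,
                               transform = "log_density_quantile",
                               subjectId = character(0)),
               deviance = 0, fitted = rep(0.5, 2L), auc = 0.5,
               basis = basis, scores = matrix(0, 2L, 1L),
               X = matrix(1, 2L, 1L), A = c(0L, 1L),
               vcov = diag(2L), transform = "log_density_quantile",
               separationFallback = FALSE)
    M <- edgeEffectMap(fit, d, sub$C)
    edgeMean <- mean(M[upper.tri(M)])
    ldq <- applyTransform(d, "log_density_quantile", grid)@values
    quad <- sum(ConnDensity:::.quadWeights(grid) * gvals * ldq)
    expect_lt(abs(edgeMean - quad) / abs(quad), 0.05)
  })
})

test_that("aggregation, cancellation and top-fraction accounting hold", {
  p <- 6L
  idx <- edgeIndex(p)
  mk <- function(v) { M <- matrix(0, p, p)
    M[cbind(idx$s, idx$t)] <- v; M[cbind(idx$t, idx$s)] <- v; M }
  M <- mk(seq(-1, 1, length.out = nrow(idx)))
  ## single subject: average equals the input
  one <- inducedConnectivity(list(M))
  expect_identical(one@averageEffect, M)
  ## equal and opposite effects cancel
  two <- inducedConnectivity(list(M, -M))
  expect_true(all(two@averageEffect == 0))
  ## identical maps select identically: frequencies are 0 or 1
  f <- consistencyFrequency(list(M, M, M), topFraction = 0.2)
  expect_true(all(f %in% c(0, 1)))
  expect_identical(sum(f[upper.tri(f)] == 1), as.integer(ceiling(0.2 * nrow(idx))))
  ## the 5% rule on 3003 edges marks 151 per subject
  expect_identical(as.integer(ceiling(0.05 * 3003)), 151L)
  ## accounting: total marks equal subjects x marks-per-subject (no ties)
  set.seed(74)
  maps <- lapply(1:5, function(i) mk(rnorm(nrow(idx))))
  fr <- consistencyFrequency(maps, topFraction = 0.2)
  expect_equal(sum(fr[upper.tri(fr)]) * 5, 5 * ceiling(0.2 * nrow(idx)))
  expect_error(inducedConnectivity(list()), "no effect maps")
  expect_error(consistencyFrequency(maps, topFraction = 1.2), "strictly in")
})

test_that("a planted tail-quantile row is localized by the average map", {
  ## oracle construction: subjects share one density whose tails carry large
  ## |log f|; treated subjects have row 5 pushed into the tail, so with a
  ## tail-weighting coefficient function the average effect must single out
  ## region 5
  withr::with_seed(75, {
    p <- 12L; n <- 20L
    idx <- edgeIndex(p)
    base <- 2 * rbeta(5000, 6, 6) - 1
    d <- fitSplineDensity(base)
    grid <- quantileGrid()
    w <- ConnDensity:::.quadWeights(grid)
    gvals <- (grid - 0.5)^2          # weights both tails, vanishes centrally
    basis <- new("FPCABasis", grid = grid, meanFunction = rep(0, 101L),
                 eigenfunctions = matrix(gvals / sqrt(sum(w * gvals^2)),
                                         ncol = 1L),
                 eigenvalues = 1, nComponents = 1L, varianceFraction = 1)
    fs <- function(v) new("FunctionSample", grid = grid, values = v,
                          transform = "log_density_quantile",
                          subjectId = character(0))
    fit <- new("DensityLogitFit", beta = c(intercept = 0),
               gamma = sqrt(sum(w * gvals^2)), g = fs(gvals),
               bandLower = fs(gvals - 1), bandUpper = fs(gvals + 1),
               deviance = 0, fitted = rep(0.5, 2L), auc = 0.5,
               basis = basis, scores = matrix(0, 2L, 1L),
               X = matrix(1, 2L, 1L), A = c(0L, 1L), vcov = diag(2L),
               transform = "log_density_quantile",
               separationFallback = FALSE)
    effects <- lapply(seq_len(n), function(i) {
      v <- sample(base, nrow(idx))
      C <- matrix(0, p, p); diag(C) <- 1
      C[cbind(idx$s, idx$t)] <- v; C[cbind(idx$t, idx$s)] <- v
      if (i <= n / 2) {           # "treated": row 5 pushed into the tail
        others <- setdiff(seq_len(p), 5L)
        C[5L, others] <- pmin(abs(C[5L, others]) + 0.55, 0.97)
        C[others, 5L] <- C[5L, others]
      }
      edgeEffectMap(fit, d, C)
    })
    ind <- inducedConnectivity(effects)
    expect_identical(unname(which.max(rowSums(abs(ind@averageEffect)))), 5L)
    ## the same region dominates the top-5% consistency frequencies
    expect_identical(unname(which.max(rowSums(ind@frequency))), 5L)
  })
})
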