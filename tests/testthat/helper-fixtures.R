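## Shared fixtures, all generated in code.

## orthonormal (trapezoid inner product) basis curves on a grid
makeBasisFunctions <- function(grid, K) {
  raw <- sapply(seq_len(K), function(k) sin(pi * k * grid) + 0.2 * k * grid)
  w <- ConnDensity:::.quadWeights(grid)
  psi <- matrix(0, length(grid), K)
  for (k in seq_len(K)) {
    v <- raw[, k]
    if (k > 1L)
      for (j in seq_len(k - 1L)) v <- v - sum(w * v * psi[, j]) * psi[, j]
    psi[, k] <- v / sqrt(sum(w * v^2))
  }
  psi
}

## synthetic functional covariates: mean + sum_k score_ik * psi_k
makeCurves <- function(n, evals, grid = quantileGrid(), seed = 1,
                       meanFun = function(q) -0.7 + 0.5 * q) {
  K <- length(evals)
  psi <- makeBasisFunctions(grid, K)
  withr::with_seed(seed, {
    scores <- sapply(evals, function(l) rnorm(n, sd = sqrt(l)))
    Y <- outer(rep(1, n), meanFun(grid)) + scores %*% t(psi)
    samples <- lapply(seq_len(n), function(i)
      new("FunctionSample", grid = grid, values = Y[i, ],
          transform = "log_density_quantile", subjectId = sprintf("S%d", i)))
    list(samples = samples, scores = scores, psi = psi, Y = Y)
  })
}

## binary labels from a single-component functional logistic model
makeCurveStudy <- function(n, gamma, evals = c(1), seed = 1,
                           grid = quantileGrid()) {
  cur <- makeCurves(n, evals, grid, seed)
  withr::with_seed(seed + 1000L, {
    eta <- drop(scale(cur$scores, scale = FALSE) %*% gamma)
    A <- rbinom(n, 1L, plogis(eta))
    ## guard against degenerate draws
    if (length(unique(A)) == 1L) A[1:2] <- c(0L, 1L)
    cov <- data.frame(A = A, intercept = 1)
    c(cur, list(cov = cov))
  })
}

## a cheap valid spline DensityEstimate with given coefficients
makeSplineDensity <- function(coef, support = c(-1, 1)) {
  setup <- ConnDensity:::.splineSetup(length(coef), support)
  new("DensityEstimate", support = support, method = "spline",
      knots = setup$knots, coefficients = coef, lambda = 0,
      logNormConst = ConnDensity:::.splineLogZ(setup, coef),
      bandwidth = numeric(0), sample = numeric(0), n = 100L)
}

## random smooth spline densities, one per subject (fast, no fitting)
makeRandomDensities <- function(n, seed = 1, sd = 0.4, nbasis = 19L) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    coef <- as.vector(stats::filter(rnorm(nbasis, sd = sd), rep(1 / 3, 3),
                                    circular = TRUE))
    makeSplineDensity(coef)
  }))
}

## a study-shaped fixture: n subjects, treated/control split, baseline
## covariates, von Mises connectivity maps with a treated-arm perturbation
makeStudyFixture <- function(n = 47L, nTreated = 25L, p = 20L, seed = 7,
                             stimulate = FALSE, w = 0.75) {
  withr::with_seed(seed, {
    A <- c(rep(1L, nTreated), rep(0L, n - nTreated))
    mats <- lapply(seq_len(n), function(i) {
      prm <- vonMisesParams(ConnDensity:::.wrapAngle(rnorm(1, 1.2, 0.3)),
                            exp(rnorm(1, log(1.5), 0.4)))
      subj <- generateSubject(prm, p)
      if (stimulate && A[i] == 1L)
        applyStimulation(subj$theta, subj$C, sample.int(p, 1L), w, pi)
      else subj$C
    })
    names(mats) <- sprintf("S%03d", seq_len(n))
    cov <- data.frame(A = A, age = round(rnorm(n, 67, 7), 1),
                      severity = round(runif(n, 0.5, 3), 2))
    ConnectivityStudy(mats, cov)
  })
}

## full density-regression fit of a study for one transform
fitStudyPipeline <- function(study, kind = "log_density_quantile",
                             grid = quantileGrid(), ...) {
  edges <- SummarizedExperiment::assay(study, "edges")
  dens <- lapply(seq_len(ncol(study)), function(i)
    fitSplineDensity(edges[, i]))
  samples <- buildFunctionalCovariates(dens, kind, grid)
  basis <- fitFPCA(samples, ...)
  fit <- suppressWarnings(fitDensityLogit(study, basis, samples))
  list(fit = fit, densities = dens, samples = samples, basis = basis)
}
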