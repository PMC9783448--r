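## Functional principal component analysis of transformed densities.

#' Build the functional covariates of a study
#'
#' Applies one transform to every subject's density estimate on a shared
#' grid, producing the functional covariates entering the regression.
#'
#' @param densities list of [DensityEstimate-class], one per subject, all on
#'   the same support.
#' @param kind transform kind, see [applyTransform()].
#' @param grid shared evaluation grid (quantile levels for quantile-indexed
#'   kinds); fixed study-wide.
#' @return list of [FunctionSample-class], one per subject, in input order.
#' @export
buildFunctionalCovariates <- function(densities,
                                      kind = "log_density_quantile",
                                      grid = quantileGrid()) {
  if (length(densities) == 0L) stop("no densities supplied")
  supports <- vapply(densities, function(d) d@support, numeric(2L))
  if (max(abs(supports - supports[, 1L])) > 0)
    stop("all densities must share the same support")
  ids <- names(densities)
  out <- lapply(seq_along(densities), function(i) {
    fs <- applyTransform(densities[[i]], kind, grid)
    if (!is.null(ids)) fs@subjectId <- ids[i]
    fs
  })
  names(out) <- ids
  out
}

## stack a list of FunctionSamples into an n x m matrix, checking equal grids
.sampleMatrix <- function(samples) {
  grid <- samples[[1L]]@grid
  for (s in samples)
    if (length(s@grid) != length(grid) || max(abs(s@grid - grid)) > 1e-12)
      stop("all functional covariates must share the same grid")
  list(grid = grid,
       Y = do.call(rbind, lapply(samples, function(s) s@values)))
}

## penalized B-spline projection smoother on a grid: S = B (B'WB + l*P)^-1 B'W
.covSmoother <- function(grid, nbasis = 15L, relPenalty = 1e-4) {
  lo <- min(grid); hi <- max(grid)
  bounds <- seq(lo, hi, length.out = nbasis - 2L)
  knots <- c(rep(lo, 3L), bounds, rep(hi, 3L))
  B <- splineDesign(knots, grid, ord = 4L)
  gl <- .gaussLegendre(3L)
  half <- diff(bounds) / 2
  mid <- (bounds[-1L] + bounds[-length(bounds)]) / 2
  n3 <- as.vector(outer(gl$nodes, half) + rep(mid, each = 3L))
  w3 <- as.vector(outer(gl$weights, half))
  B2 <- splineDesign(knots, n3, ord = 4L, derivs = rep(2L, length(n3)))
  P <- crossprod(B2 * sqrt(w3))
  W <- .trapzWeights(grid)
  M <- crossprod(B * W, B)
  lambda <- relPenalty * sum(diag(M)) / max(sum(diag(P)), 1e-12)
  B %*% solve(M + lambda * P, t(B * W))
}

#' Functional PCA of transformed density curves
#'
#' Karhunen-Loeve decomposition of the sample covariance of the functional
#' covariates on their shared grid.  By default the covariance surface is
#' lightly smoothed by a penalized bivariate B-spline projection before the
#' eigendecomposition, which suppresses estimation noise in the per-subject
#' curves; set `smoothCovariance = FALSE` for the raw sample covariance.
#' The smallest K with cumulative eigenvalue fraction at or above
#' `varianceThreshold` is retained.  Eigenfunctions are orthonormal under
#' the grid quadrature inner product (midpoint rule on quantile-level grids, trapezoid otherwise).
#'
#' @param samples list of [FunctionSample-class] on a common grid.
#' @param varianceThreshold fraction of variance to retain, in (0, 1]
#'   (default 0.99).
#' @param smoothCovariance logical, default TRUE.
#' @return an [FPCABasis-class].
#' @export
fitFPCA <- function(samples, varianceThreshold = 0.99,
                    smoothCovariance = TRUE) {
  if (varianceThreshold <= 0 || varianceThreshold > 1)
    stop("varianceThreshold must lie in (0, 1]")
  if (length(samples) < 3L) stop("need at least 3 subjects for fPCA")
  sm <- .sampleMatrix(samples)
  grid <- sm$grid
  Y <- sm$Y
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2L, mu)
  Cov <- crossprod(Yc) / (nrow(Y) - 1L)
  if (smoothCovariance) {
    S <- .covSmoother(grid)
    Cov <- S %*% Cov %*% t(S)
    Cov <- (Cov + t(Cov)) / 2
  }
  w <- .quadWeights(grid)
  sw <- sqrt(w)
  E <- eigen(t(Cov * sw) * sw, symmetric = TRUE)
  vals <- pmax(E$values, 0)
  tot <- sum(vals)
  if (tot <= 0) stop("degenerate covariance: curves are constant")
  K <- which(cumsum(vals) / tot >= varianceThreshold - 1e-12)[1L]
  phi <- E$vectors[, seq_len(K), drop = FALSE] / sw
  ## sign convention: make each eigenfunction's largest-magnitude value positive
  for (k in seq_len(K)) {
    j <- which.max(abs(phi[, k]))
    if (phi[j, k] < 0) phi[, k] <- -phi[, k]
  }
  new("FPCABasis", grid = grid, meanFunction = mu, eigenfunctions = phi,
      eigenvalues = vals, nComponents = as.integer(K),
      varianceFraction = sum(vals[seq_len(K)]) / tot)
}

#' Principal component scores of curves under an FPCA basis
#'
#' Uncentered quadrature inner products (midpoint rule on quantile grids) of each curve with the retained
#' eigenfunctions.  Uncentered scores keep the functional linear predictor
#' equal to the direct quadrature of each curve against the coefficient
#' function (the mean offset is absorbed by the model intercept).
#'
#' @param basis an [FPCABasis-class].
#' @param samples list of [FunctionSample-class] on the basis grid.
#' @return n x K numeric matrix of scores.
#' @export
fpcaScores <- function(basis, samples) {
  sm <- .sampleMatrix(samples)
  if (max(abs(sm$grid - basis@grid)) > 1e-12)
    stop("curve grid does not match the FPCA basis grid")
  w <- .quadWeights(basis@grid)
  sm$Y %*% (basis@eigenfunctions * w)
}

setMethod("show", "FPCABasis", function(object) {
  cat(sprintf(
    "FPCABasis: %d components on %d grid points (%.2f%% of variance)\n",
    object@nComponents, length(object@grid),
    100 * object@varianceFraction))
})
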