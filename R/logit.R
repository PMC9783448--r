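## The inverse case-control functional logistic regression and its inference.

#' @importFrom stats glm.fit binomial pchisq plogis qnorm
NULL

## extract (A, X) from a ConnectivityStudy or a covariate data.frame
.covParts <- function(cov) {
  if (is(cov, "SummarizedExperiment")) {
    A <- treatmentLabels(cov)
    X <- designMatrix(cov)
  } else {
    cov <- as.data.frame(cov)
    if (!"A" %in% colnames(cov)) stop("covariate table must contain column A")
    A <- as.integer(cov$A)
    X <- designMatrix(cov)
  }
  if (!all(A %in% c(0L, 1L))) stop("treatment label A must be binary 0/1")
  list(A = A, X = X)
}

## binomial deviance for 0/1 outcomes
.binDeviance <- function(y, p) -2 * sum(y * log(p) + (1 - y) * log(1 - p))

## ridge-penalized logistic Newton fit (used as the separation fallback)
.ridgeLogit <- function(D, y, lambda = 1e-4, maxit = 100L) {
  theta <- numeric(ncol(D))
  for (it in seq_len(maxit)) {
    eta <- drop(D %*% theta)
    p <- plogis(eta)
    g <- drop(crossprod(D, y - p)) - lambda * theta
    W <- p * (1 - p)
    H <- crossprod(D * W, D) + lambda * diag(ncol(D))
    step <- solve(H, g)
    theta <- theta + step
    if (max(abs(g)) < 1e-10) break
  }
  eta <- drop(D %*% theta)
  p <- plogis(eta)
  W <- p * (1 - p)
  H <- crossprod(D * W, D) + lambda * diag(ncol(D))
  list(coef = theta, fitted = p, vcov = solve(H))
}

#' Fit the density-regression logistic model
#'
#' Maximum-likelihood logistic regression of the binary treatment label on
#' the baseline covariates plus the functional principal component scores of
#' the transformed connection densities.  The coefficient function g is the
#' eigenfunction expansion of the score coefficients, reported with 95%
#' pointwise bands from the inverse observed information (a Bayesian
#' posterior-covariance argument for penalized spline fits).
#'
#' Perfect separation, plausible at small n with many components, triggers a
#' ridge-stabilized refit (L2 penalty 1e-4) with a warning; the fit records
#' the fallback in `separationFallback`.
#'
#' @param cov a [ConnectivityStudy-class] or a covariate data.frame with a
#'   binary column `A` and baseline covariates.
#' @param basis the [FPCABasis-class] of the functional covariates.
#' @param samples list of [FunctionSample-class] in subject order.
#' @return a [DensityLogitFit-class].
#' @export
fitDensityLogit <- function(cov, basis, samples) {
  parts <- .covParts(cov)
  A <- parts$A; X <- parts$X
  n <- length(A)
  if (length(samples) != n)
    stop("number of functional covariates does not match subjects")
  if (length(unique(A)) < 2L) stop("treatment labels are all equal")
  S <- fpcaScores(basis, samples)
  K <- ncol(S)
  q <- ncol(X)
  if (n <= q + K)
    stop(sprintf("model not identifiable: n = %d subjects but q + K = %d",
                 n, q + K))
  ## drop numerically-zero score columns (degenerate functional term)
  active <- apply(S, 2L, function(s) max(abs(s)) > 1e-12)
  D <- cbind(X, S[, active, drop = FALSE])
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    nm <- c(colnames(X), paste0("PC", which(active)))
    bad <- nm[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(glm.fit(D, A, family = binomial()))
  separated <- !fit$converged ||
    any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  if (separated) {
    warning("separation detected; refitting with an L2 penalty of 1e-4")
    rf <- .ridgeLogit(D, A)
    coefs <- rf$coef; fitted <- rf$fitted; V <- rf$vcov
  } else {
    coefs <- fit$coefficients
    fitted <- fit$fitted.values
    W <- fitted * (1 - fitted)
    V <- solve(crossprod(D * W, D))
  }
  ## re-expand to the full (q + K) coefficient vector
  beta <- coefs[seq_len(q)]
  gamma <- numeric(K)
  gamma[active] <- coefs[-seq_len(q)]
  Vfull <- matrix(0, q + K, q + K)
  idx <- c(seq_len(q), q + which(active))
  Vfull[idx, idx] <- V
  fitted <- pmin(pmax(fitted, 1e-12), 1 - 1e-12)
  gvals <- drop(basis@eigenfunctions %*% gamma)
  Vg <- Vfull[(q + 1L):(q + K), (q + 1L):(q + K), drop = FALSE]
  se <- sqrt(pmax(rowSums((basis@eigenfunctions %*% Vg) *
                            basis@eigenfunctions), 0))
  z <- qnorm(0.975)
  mk <- function(v) new("FunctionSample", grid = basis@grid, values = v,
                        transform = samples[[1L]]@transform,
                        subjectId = character(0))
  new("DensityLogitFit",
      beta = stats::setNames(beta, colnames(X)), gamma = gamma,
      g = mk(gvals), bandLower = mk(gvals - z * se),
      bandUpper = mk(gvals + z * se),
      deviance = .binDeviance(A, fitted), fitted = fitted,
      auc = .rankAUC(fitted, A), basis = basis, scores = S, X = X,
      A = as.integer(A), vcov = Vfull,
      transform = samples[[1L]]@transform,
      separationFallback = separated)
}

#' Pointwise confidence band for the coefficient function
#'
#' Recomputes g(q) +/- z * se(q) at an arbitrary level, propagating the
#' posterior/inverse-information covariance of the score coefficients
#' through the eigenfunctions.
#'
#' @param fit a [DensityLogitFit-class].
#' @param level coverage level in (0, 1), default 0.95.
#' @return list with `lower` and `upper` [FunctionSample-class] curves.
#' @export
coefficientBand <- function(fit, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must lie strictly in (0, 1)")
  if (fit@separationFallback)
    warning("bands from a ridge-stabilized fit; interpret with caution")
  basis <- fit@basis
  q <- length(fit@beta); K <- length(fit@gamma)
  Vg <- fit@vcov[(q + 1L):(q + K), (q + 1L):(q + K), drop = FALSE]
  se <- sqrt(pmax(rowSums((basis@eigenfunctions %*% Vg) *
                            basis@eigenfunctions), 0))
  z <- qnorm(1 - (1 - level) / 2)
  mk <- function(v) new("FunctionSample", grid = basis@grid, values = v,
                        transform = fit@g@transform,
                        subjectId = character(0))
  list(lower = mk(fit@g@values - z * se), upper = mk(fit@g@values + z * se))
}

#' Likelihood ratio test against the baseline-covariate model
#'
#' Compares the full density-regression fit with the nested logistic model
#' using only the baseline covariates.  The statistic is the deviance drop;
#' reference distribution chi-square with K degrees of freedom.
#'
#' @param fit a [DensityLogitFit-class].
#' @param cov the same covariate source the fit used.
#' @param bonferroni number of transforms compared; the returned
#'   `pAdjusted` multiplies p by this count (capped at 1).  Default 1.
#' @return list with `statistic`, `df`, `p`, `pAdjusted`.
#' @export
lrtVsBaseline <- function(fit, cov, bonferroni = 1L) {
  parts <- .covParts(cov)
  if (length(parts$A) != length(fit@A) || any(parts$A != fit@A) ||
      !isTRUE(all.equal(unname(parts$X), unname(fit@X), tolerance = 1e-12)))
    stop("models are not nested on identical subjects")
  base <- suppressWarnings(glm.fit(fit@X, fit@A, family = binomial()))
  stat <- max(base$deviance - fit@deviance, 0)
  df <- length(fit@gamma)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p,
       pAdjusted = min(1, p * bonferroni))
}

#' Permutation AUC test for the functional term
#'
#' Builds the null distribution of the in-sample AUC by randomly shuffling
#' which connection density belongs to which subject (the covariate rows
#' stay fixed) and refitting the logistic model.  Because the set of curves
#' is unchanged, the FPCA basis is permutation-invariant and only the score
#' rows shuffle.  The p-value uses the add-one permutation convention.
#'
#' @param cov covariate source (see [fitDensityLogit()]).
#' @param densities list of [DensityEstimate-class] in subject order.
#' @param kind transform kind (default log density quantile).
#' @param grid shared quantile grid.
#' @param B number of permutations (default 20000).
#' @param seed RNG seed for the permutations.
#' @param varianceThreshold,smoothCovariance passed to [fitFPCA()].
#' @return list with `p`, `mcse`, `observedAuc`, `B`.
#' @export
permutationAucTest <- function(cov, densities, kind = "log_density_quantile",
                               grid = quantileGrid(), B = 20000L,
                               seed = NULL, varianceThreshold = 0.99,
                               smoothCovariance = TRUE) {
  if (B < 100L) stop("need at least 100 permutations")
  if (B < 1000L)
    warning("fewer than 1000 permutations: p-value resolution is coarse")
  samples <- buildFunctionalCovariates(densities, kind, grid)
  basis <- fitFPCA(samples, varianceThreshold, smoothCovariance)
  parts <- .covParts(cov)
  A <- parts$A; X <- parts$X
  S <- fpcaScores(basis, samples)
  fitAuc <- function(Sperm) {
    f <- suppressWarnings(glm.fit(cbind(X, Sperm), A, family = binomial()))
    .rankAUC(f$fitted.values, A)
  }
  observed <- fitAuc(S)
  n <- length(A)
  exceed <- .withSeed(seed, {
    cnt <- 0L
    for (b in seq_len(B))
      if (fitAuc(S[sample.int(n), , drop = FALSE]) >= observed)
        cnt <- cnt + 1L
    cnt
  })
  p <- (1 + exceed) / (B + 1)
  list(p = p, mcse = sqrt(p * (1 - p) / B), observedAuc = observed, B = B)
}

#' Linear functional score of a subject's density
#'
#' The scalar summary integral of the transformed density against the fitted
#' coefficient function, by trapezoid quadrature on the fit grid.  For a
#' training subject it equals the subject's functional linear predictor.
#'
#' @param fit a [DensityLogitFit-class].
#' @param d a [DensityEstimate-class].
#' @param kind transform kind; must match the fit.
#' @param grid evaluation grid; must match the fit grid.
#' @return a single numeric score.
#' @export
linearFunctionalScore <- function(fit, d, kind = fit@transform,
                                  grid = fit@basis@grid) {
  if (!identical(kind, fit@transform))
    stop("transform kind does not match the fitted model")
  if (length(grid) != length(fit@basis@grid) ||
      max(abs(grid - fit@basis@grid)) > 1e-12)
    stop("grid does not match the fitted model grid")
  fs <- applyTransform(d, kind, grid)
  sum(.quadWeights(grid) * fs@values * fit@g@values)
}

setMethod("show", "DensityLogitFit", function(object) {
  cat(sprintf(
    "DensityLogitFit (%s transform): n = %d, K = %d components\n",
    object@transform, length(object@A), length(object@gamma)))
  cat(sprintf("  deviance %.3f, in-sample AUC %.3f%s\n", object@deviance,
              object@auc,
              if (object@separationFallback) " [ridge fallback]" else ""))
  cat("  beta:", paste(sprintf("%s=%.3f", names(object@beta), object@beta),
                       collapse = ", "), "\n")
})
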