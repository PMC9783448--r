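## Localized comparison methods: edgewise logistic scans and principal
## component regression on the vectorized connectivity matrix.

#' @importFrom stats p.adjust prcomp
NULL

#' Edgewise logistic scan with familywise correction
#'
#' Fits one logistic regression of the treatment label on the baseline
#' covariates plus a single edge's correlation, for every region pair, and
#' tests the edge coefficient by a Wald test.  Familywise control is by
#' Bonferroni over all p(p-1)/2 edges (Benjamini-Hochberg available behind
#' `correction = "BH"`, never the default).  An edge whose fit separates is
#' conservatively assigned p = 1.
#'
#' @param study a [ConnectivityStudy-class].
#' @param alpha familywise level for the positive-finding flag.
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @return an [EdgewiseResult-class].
#' @export
edgewiseScan <- function(study, alpha = 0.05, correction = "bonferroni") {
  parts <- .covParts(study)
  A <- parts$A; X <- parts$X
  n <- length(A)
  if (n <= ncol(X) + 1L)
    stop("too few subjects for an edgewise fit")
  E <- assay(study, "edges")
  m <- nrow(E)
  coefs <- numeric(m); pRaw <- numeric(m); nSep <- 0L
  fam <- binomial()
  for (e in seq_len(m)) {
    D <- cbind(X, edge = E[e, ])
    f <- suppressWarnings(glm.fit(D, A, family = fam))
    sep <- !f$converged ||
      any(f$fitted.values < 1e-8 | f$fitted.values > 1 - 1e-8)
    j <- ncol(D)
    if (sep || is.na(f$coefficients[j])) {
      coefs[e] <- f$coefficients[j]
      pRaw[e] <- 1
      nSep <- nSep + 1L
    } else {
      W <- f$fitted.values * (1 - f$fitted.values)
      V <- tryCatch(solve(crossprod(D * W, D)), error = function(err) NULL)
      if (is.null(V)) { pRaw[e] <- 1; nSep <- nSep + 1L; next }
      z <- f$coefficients[j] / sqrt(V[j, j])
      coefs[e] <- f$coefficients[j]
      pRaw[e] <- 2 * pnorm(-abs(z))
    }
  }
  correction <- match.arg(correction, c("bonferroni", "BH"))
  pAdj <- if (correction == "BH") p.adjust(pRaw, "BH") else
    pmin(1, pRaw * m)
  new("EdgewiseResult", s = rowData(study)$s, t = rowData(study)$t,
      coefficient = coefs, pRaw = pRaw, pAdjusted = pAdj,
      familySize = as.integer(m), anyPositive = any(pAdj <= alpha),
      alpha = alpha, correction = correction, nSeparated = nSep)
}

#' Principal component regression on vectorized connectivity
#'
#' PCA of the n x p(p-1)/2 matrix of vectorized upper triangles; the leading
#' components reaching `varianceThreshold` of the variance (capped at
#' n - q - 1 for identifiability) enter a logistic regression with the
#' baseline covariates.  Each component coefficient gets a Wald test,
#' Bonferroni-corrected over the retained K.
#'
#' @param study a [ConnectivityStudy-class].
#' @param varianceThreshold retained variance fraction, default 0.99.
#' @param alpha familywise level for the positive-finding flag.
#' @return a [PCRegressionResult-class].
#' @export
pcRegression <- function(study, varianceThreshold = 0.99, alpha = 0.05) {
  if (varianceThreshold <= 0 || varianceThreshold > 1)
    stop("varianceThreshold must lie in (0, 1]")
  parts <- .covParts(study)
  A <- parts$A; X <- parts$X
  n <- length(A)
  if (n < 3L) stop("need at least 3 subjects")
  Y <- t(assay(study, "edges"))
  pc <- prcomp(Y, center = TRUE, scale. = FALSE)
  varFrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  K <- which(varFrac >= varianceThreshold - 1e-12)[1L]
  truncated <- FALSE
  Kmax <- n - ncol(X) - 1L
  if (K > Kmax) {
    warning(sprintf("retained components truncated from %d to %d (n - q - 1)",
                    K, Kmax))
    K <- Kmax
    truncated <- TRUE
  }
  S <- pc$x[, seq_len(K), drop = FALSE]
  D <- cbind(X, S)
  f <- suppressWarnings(glm.fit(D, A, family = binomial()))
  W <- f$fitted.values * (1 - f$fitted.values)
  V <- tryCatch(solve(crossprod(D * W, D)), error = function(err) NULL)
  idx <- ncol(X) + seq_len(K)
  if (is.null(V)) {
    pRaw <- rep(1, K)
    coefs <- f$coefficients[idx]
  } else {
    z <- f$coefficients[idx] / sqrt(diag(V)[idx])
    pRaw <- 2 * pnorm(-abs(z))
    pRaw[!is.finite(pRaw)] <- 1
    coefs <- f$coefficients[idx]
  }
  pAdj <- pmin(1, pRaw * K)
  new("PCRegressionResult", nComponents = as.integer(K), scores = S,
      coefficient = coefs, pRaw = pRaw, pAdjusted = pAdj,
      anyPositive = any(pAdj <= alpha), alpha = alpha,
      truncated = truncated)
}

setMethod("show", "EdgewiseResult", function(object) {
  cat(sprintf(
    "EdgewiseResult: %d edge tests, min adjusted p = %.4g, %s at alpha = %g\n",
    object@familySize, min(object@pAdjusted),
    if (object@anyPositive) "positive" else "no positive finding",
    object@alpha))
  if (object@nSeparated > 0L)
    cat(sprintf("  %d separated edges assigned p = 1\n", object@nSeparated))
})

setMethod("show", "PCRegressionResult", function(object) {
  cat(sprintf(
    "PCRegressionResult: K = %d components%s, min adjusted p = %.4g, %s\n",
    object@nComponents, if (object@truncated) " (truncated)" else "",
    min(object@pAdjusted),
    if (object@anyPositive) "positive" else "no positive finding"))
})
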