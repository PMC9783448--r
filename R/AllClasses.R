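#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core value classes
## ---------------------------------------------------------------------------

#' EdgeSample: vectorized upper triangle of a connectivity matrix
#'
#' Holds the p(p-1)/2 off-diagonal correlations of one subject's symmetric
#' connectivity matrix in canonical row-major (s < t) order, together with the
#' region-pair index of each edge.
#'
#' @slot subjectId single identifier.
#' @slot values numeric vector of edge correlations in [-1, 1].
#' @slot s,t integer vectors of 1-based region indices with s < t.
#' @exportClass EdgeSample
setClass("EdgeSample",
  slots = c(subjectId = "character", values = "numeric",
            s = "integer", t = "integer"))

setValidity("EdgeSample", function(object) {
  v <- object@values
  if (length(v) != length(object@s) || length(v) != length(object@t))
    return("values and edge indices differ in length")
  if (any(!is.finite(v))) return("edge values must be finite")
  if (any(object@s >= object@t)) return("edge indices must satisfy s < t")
  key <- paste(object@s, object@t)
  if (anyDuplicated(key)) return("duplicated edge indices")
  p <- max(object@t)
  if (length(v) != p * (p - 1) / 2)
    return(sprintf("expected %d edges for p = %d regions, got %d",
                   p * (p - 1) / 2, p, length(v)))
  TRUE
})

#' DensityEstimate: a connection density on a bounded support
#'
#' A boundary-aware density estimate for one subject's edge correlations,
#' either a penalized log-spline maximum-likelihood fit or a Gaussian kernel
#' estimate renormalized to the support.  Provides exact pdf/cdf evaluation
#' (see [evaluateDensity()]), quantile inversion ([invertCdf()]) and the
#' functional transforms ([applyTransform()]).
#'
#' @slot support numeric length-2, closed support interval (default c(-1, 1)).
#' @slot method `"spline"` or `"kernel"`.
#' @slot knots full cubic B-spline knot sequence (spline method).
#' @slot coefficients log-density spline coefficients (spline method).
#' @slot lambda nonnegative roughness-penalty weight used in the fit.
#' @slot logNormConst log of the normalization constant of exp(spline).
#' @slot bandwidth Gaussian kernel bandwidth (kernel method).
#' @slot sample sorted data values (kernel method keeps them for evaluation).
#' @slot n number of observations the estimate was fitted to.
#' @exportClass DensityEstimate
setClass("DensityEstimate",
  slots = c(support = "numeric", method = "character", knots = "numeric",
            coefficients = "numeric", lambda = "numeric",
            logNormConst = "numeric", bandwidth = "numeric",
            sample = "numeric", n = "integer"))

setValidity("DensityEstimate", function(object) {
  if (length(object@support) != 2L || diff(object@support) <= 0)
    return("support must be an increasing length-2 interval")
  if (!object@method %in% c("spline", "kernel"))
    return("method must be 'spline' or 'kernel'")
  if (object@method == "kernel") {
    if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
      return("kernel method needs a positive bandwidth")
    if (length(object@sample) == 0L)
      return("kernel method needs the data sample")
  } else {
    if (length(object@coefficients) + 4L != length(object@knots))
      return("knots/coefficients length mismatch for cubic splines")
  }
  TRUE
})

#' FunctionSample: one transformed density evaluated on a shared grid
#'
#' @slot grid strictly increasing evaluation grid (quantile levels in (0,1)
#'   for the quantile-indexed transforms, support points otherwise).
#' @slot values function values at `grid`.
#' @slot transform one of `"identity"`, `"log"`, `"quantile"`,
#'   `"log_density_quantile"`.
#' @slot subjectId optional identifier.
#' @exportClass FunctionSample
setClass("FunctionSample",
  slots = c(grid = "numeric", values = "numeric", transform = "character",
            subjectId = "character"))

setValidity("FunctionSample", function(object) {
  if (length(object@grid) != length(object@values))
    return("grid and values differ in length")
  if (any(diff(object@grid) <= 0)) return("grid must be strictly increasing")
  if (!object@transform %in%
      c("identity", "log", "quantile", "log_density_quantile"))
    return("unknown transform kind")
  TRUE
})

## ---------------------------------------------------------------------------
## Functional regression classes
## ---------------------------------------------------------------------------

#' FPCABasis: functional principal components of transformed densities
#'
#' Karhunen-Loeve decomposition of the (optionally smoothed) sample covariance
#' of functional covariates on a shared grid.  Eigenfunctions are orthonormal
#' under the grid quadrature inner product.
#'
#' @slot grid shared evaluation grid.
#' @slot meanFunction pointwise mean curve.
#' @slot eigenfunctions m x K matrix, columns orthonormal on the grid.
#' @slot eigenvalues all nonnegative eigenvalues, nonincreasing.
#' @slot nComponents K, the retained component count.
#' @slot varianceFraction cumulative variance fraction of the retained K.
#' @exportClass FPCABasis
setClass("FPCABasis",
  slots = c(grid = "numeric", meanFunction = "numeric",
            eigenfunctions = "matrix", eigenvalues = "numeric",
            nComponents = "integer", varianceFraction = "numeric"))

setValidity("FPCABasis", function(object) {
  if (nrow(object@eigenfunctions) != length(object@grid))
    return("eigenfunction rows must match grid length")
  if (ncol(object@eigenfunctions) != object@nComponents)
    return("eigenfunction columns must match nComponents")
  if (any(diff(object@eigenvalues) > 1e-8))
    return("eigenvalues must be nonincreasing")
  w <- .quadWeights(object@grid)
  G <- crossprod(object@eigenfunctions * w, object@eigenfunctions)
  if (max(abs(G - diag(object@nComponents))) > 1e-6)
    return("eigenfunctions not orthonormal under the grid quadrature inner product")
  TRUE
})

#' DensityLogitFit: the fitted scalar-on-function logistic model
#'
#' Inverse case-control logit of treatment assignment on baseline covariates
#' plus functional principal component scores of the transformed connection
#' densities.  The coefficient function g is reconstructed from the score
#' coefficients and the eigenfunctions; 95% pointwise Bayesian bands come from
#' the inverse information of the joint coefficient vector.
#'
#' @slot beta baseline covariate coefficients.
#' @slot gamma PC score coefficients.
#' @slot g coefficient function as a [FunctionSample-class].
#' @slot bandLower,bandUpper pointwise confidence band curves.
#' @slot deviance residual deviance of the fit.
#' @slot fitted fitted treatment probabilities, in (0, 1).
#' @slot auc in-sample area under the ROC curve.
#' @slot basis the [FPCABasis-class] used.
#' @slot scores n x K score matrix (uncentered inner products).
#' @slot X baseline design matrix (first column the intercept).
#' @slot A binary treatment labels.
#' @slot vcov joint covariance of (beta, gamma).
#' @slot transform transform kind of the functional covariates.
#' @slot separationFallback TRUE when a ridge-stabilized refit was used.
#' @exportClass DensityLogitFit
setClass("DensityLogitFit",
  slots = c(beta = "numeric", gamma = "numeric", g = "FunctionSample",
            bandLower = "FunctionSample", bandUpper = "FunctionSample",
            deviance = "numeric", fitted = "numeric", auc = "numeric",
            basis = "FPCABasis", scores = "matrix", X = "matrix",
            A = "integer", vcov = "matrix", transform = "character",
            separationFallback = "logical"))

setValidity("DensityLogitFit", function(object) {
  if (any(object@fitted <= 0 | object@fitted >= 1))
    return("fitted probabilities must lie strictly in (0, 1)")
  recon <- drop(object@basis@eigenfunctions %*% object@gamma)
  if (max(abs(recon - object@g@values)) > 1e-10)
    return("g must equal the eigenfunction expansion of gamma")
  if (any(object@bandLower@values > object@g@values + 1e-12) ||
      any(object@bandUpper@values < object@g@values - 1e-12))
    return("bands must bracket g pointwise")
  TRUE
})

## ---------------------------------------------------------------------------
## Baseline comparator classes
## ---------------------------------------------------------------------------

#' EdgewiseResult: per-edge logistic scan with familywise correction
#'
#' @slot s,t region indices of each tested edge.
#' @slot coefficient per-edge logistic slope.
#' @slot pRaw,pAdjusted raw and Bonferroni-adjusted Wald p-values.
#' @slot familySize number of tests, p(p-1)/2.
#' @slot anyPositive TRUE when any adjusted p-value is at or below alpha.
#' @slot alpha familywise level used for the positivity call.
#' @slot correction `"bonferroni"` (default) or `"BH"`.
#' @slot nSeparated edges whose fit separated (p set to 1, conservative).
#' @exportClass EdgewiseResult
setClass("EdgewiseResult",
  slots = c(s = "integer", t = "integer", coefficient = "numeric",
            pRaw = "numeric", pAdjusted = "numeric", familySize = "integer",
            anyPositive = "logical", alpha = "numeric",
            correction = "character", nSeparated = "integer"))

setValidity("EdgewiseResult", function(object) {
  if (length(object@pRaw) != object@familySize)
    return("familySize must equal the number of tested edges")
  if (object@correction == "bonferroni" &&
      max(abs(object@pAdjusted -
              pmin(1, object@pRaw * object@familySize))) > 1e-12)
    return("pAdjusted must be the Bonferroni adjustment of pRaw")
  ok <- any(object@pAdjusted <= object@alpha)
  if (!identical(ok, object@anyPositive))
    return("anyPositive inconsistent with adjusted p-values")
  TRUE
})

#' PCRegressionResult: principal-component regression on vectorized edges
#'
#' @slot nComponents retained component count K.
#' @slot scores n x K principal component scores.
#' @slot coefficient K logistic slopes.
#' @slot pRaw,pAdjusted Wald p-values, Bonferroni over K.
#' @slot anyPositive familywise detection flag at `alpha`.
#' @slot alpha level used.
#' @slot truncated TRUE when K was capped at n - q - 1.
#' @exportClass PCRegressionResult
setClass("PCRegressionResult",
  slots = c(nComponents = "integer", scores = "matrix",
            coefficient = "numeric", pRaw = "numeric", pAdjusted = "numeric",
            anyPositive = "logical", alpha = "numeric",
            truncated = "logical"))

## ---------------------------------------------------------------------------
## Simulation classes
## ---------------------------------------------------------------------------

#' VonMisesParams: location/concentration of a circular edge-angle law
#'
#' @slot mu mean direction in radians, wrapped to [-pi, pi).
#' @slot kappa nonnegative concentration.
#' @exportClass VonMisesParams
setClass("VonMisesParams", slots = c(mu = "numeric", kappa = "numeric"))

setValidity("VonMisesParams", function(object) {
  if (object@kappa < 0) return("kappa must be nonnegative")
  if (object@mu < -pi || object@mu >= pi)
    return("mu must be wrapped to [-pi, pi)")
  TRUE
})

#' SimulationConfig: settings of the von Mises stimulation benchmark
#'
#' Defaults reproduce the benchmark's study conditions: 20 regions, 50
#' subjects, half stimulated, rotation phi = pi mixed with weight w = 0.75.
#' The subject-level (mu, kappa) population is a wrapped-normal /
#' log-normal prior standing in for parameters fitted to real scans.
#'
#' @slot nRegions,nSubjects map size and sample size.
#' @slot stimulatedFraction fraction of subjects stimulated.
#' @slot w convex-combination weight of the pre-stimulation matrix.
#' @slot phi rotation angle applied to stimulated-region edges (radians).
#' @slot scenario `"null"`, `"nonlocalized"`, or `"localized"`.
#' @slot localizedRegion fixed stimulated region (localized scenario only).
#' @slot muCenter,muSpread wrapped-normal prior on subject mean directions.
#' @slot kappaLogMean,kappaLogSd log-normal prior on subject concentrations.
#' @slot nReps benchmark replicate count.
#' @slot alpha per-method decision level.
#' @slot seed master seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(nRegions = "integer", nSubjects = "integer",
            stimulatedFraction = "numeric", w = "numeric", phi = "numeric",
            scenario = "character", localizedRegion = "integer",
            muCenter = "numeric", muSpread = "numeric",
            kappaLogMean = "numeric", kappaLogSd = "numeric",
            nReps = "integer", alpha = "numeric", seed = "integer"),
  prototype = list(nRegions = 20L, nSubjects = 50L,
                   stimulatedFraction = 0.5, w = 0.75, phi = pi,
                   scenario = "nonlocalized", localizedRegion = NA_integer_,
                   muCenter = 1.2, muSpread = 0.3,
                   kappaLogMean = log(1.5), kappaLogSd = 0.4,
                   nReps = 1000L, alpha = 0.05, seed = 1L))

setValidity("SimulationConfig", function(object) {
  if (object@nRegions < 3L) return("need at least 3 regions")
  if (object@w < 0 || object@w > 1) return("w must lie in [0, 1]")
  nStim <- object@stimulatedFraction * object@nSubjects
  if (!.isWholeNumber(nStim))
    return("stimulatedFraction * nSubjects must be an integer")
  if (!object@scenario %in% c("null", "nonlocalized", "localized"))
    return("unknown scenario")
  if (object@scenario == "localized" &&
      (is.na(object@localizedRegion) ||
       object@localizedRegion < 1L || object@localizedRegion > object@nRegions))
    return("localizedRegion must name a region for the localized scenario")
  TRUE
})

#' BenchmarkResult: per-method positive-finding rates over replicates
#'
#' @slot decisions nReps x nMethods logical matrix of per-replicate detections.
#' @slot rates per-method positive rates.
#' @slot se binomial Monte Carlo standard errors.
#' @slot nReps replicate count actually used.
#' @slot nFailed replicates excluded because a method errored.
#' @slot config the [SimulationConfig-class] used.
#' @exportClass BenchmarkResult
setClass("BenchmarkResult",
  slots = c(decisions = "matrix", rates = "numeric", se = "numeric",
            nReps = "integer", nFailed = "integer",
            config = "SimulationConfig"))

setValidity("BenchmarkResult", function(object) {
  r <- colMeans(object@decisions)
  if (max(abs(r - object@rates)) > 1e-12)
    return("rates must be the column means of decisions")
  TRUE
})

## ---------------------------------------------------------------------------
## Induced-connectivity diagnostic
## ---------------------------------------------------------------------------

#' InducedConnectivity: localization diagnostic of the fitted density model
#'
#' Per-edge stimulation-induced effects g(Q_st) * log f(C_st) averaged across
#' subjects, with the cross-subject frequency of each edge landing in the top
#' fraction of absolute effects.
#'
#' @slot averageEffect p x p symmetric matrix, zero diagonal.
#' @slot frequency p x p selection-frequency matrix in [0, 1], zero diagonal.
#' @slot topFraction fraction of edges marked per subject (default 0.05).
#' @slot nSubjects number of subjects averaged.
#' @exportClass InducedConnectivity
setClass("InducedConnectivity",
  slots = c(averageEffect = "matrix", frequency = "matrix",
            topFraction = "numeric", nSubjects = "integer"))

setValidity("InducedConnectivity", function(object) {
  A <- object@averageEffect; F <- object@frequency
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-10)))
    return("averageEffect must be symmetric")
  if (any(abs(diag(A)) > 0) || any(abs(diag(F)) > 0))
    return("diagonals must be zero")
  if (any(F < 0 | F > 1)) return("frequencies must lie in [0, 1]")
  TRUE
})
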