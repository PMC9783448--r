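#' @importFrom stats bw.nrd0
NULL

#' Fit a Gaussian kernel density renormalized to the support
#'
#' Gaussian kernel density estimate with Silverman's rule-of-thumb bandwidth
#' by default.  Boundary bias at the ends of the correlation range is removed
#' by reflecting the data about both support endpoints, and the reflected
#' estimate is renormalized so it integrates to exactly one on the support.
#' Both the pdf and the cdf have closed forms (Gaussian mixtures), so
#' evaluation is exact rather than gridded.  Provided as a cross-check on the
#' log-spline fit; the spline form is the default elsewhere because it is
#' strictly positive on the support.
#'
#' @param x an [EdgeSample-class] or numeric vector of correlations.
#' @param bandwidth `"auto"` (Silverman) or a positive number.
#' @param support closed support interval, default `c(-1, 1)`.
#' @return a [DensityEstimate-class] with `method = "kernel"`.
#' @export
fitKernelDensity <- function(x, bandwidth = "auto", support = c(-1, 1)) {
  vals <- if (is(x, "EdgeSample")) x@values else as.numeric(x)
  if (length(unique(vals)) < 20L)
    stop("degenerate sample: need at least 20 distinct edge values, got ",
         length(unique(vals)))
  eps <- 1e-6
  vals <- pmin(pmax(vals, support[1L] + eps), support[2L] - eps)
  vals <- sort(vals)                       # canonical order: label invariance
  if (identical(bandwidth, "auto")) {
    bandwidth <- bw.nrd0(vals)
  } else {
    bandwidth <- as.numeric(bandwidth)
    if (!is.finite(bandwidth) || bandwidth <= 0)
      stop("bandwidth must be 'auto' or a positive number")
  }
  new("DensityEstimate", support = support, method = "kernel",
      knots = numeric(0), coefficients = numeric(0), lambda = 0,
      logNormConst = NA_real_, bandwidth = bandwidth, sample = vals,
      n = length(vals))
}

## data augmented with reflections about both support endpoints
.kernelCenters <- function(d) {
  c(d@sample, 2 * d@support[1L] - d@sample, 2 * d@support[2L] - d@sample)
}

## mass of the reflected mixture on the support (for exact renormalization;
## this is 1 up to the far-tail leakage of the reflected kernels)
.kernelMass <- function(d, centers) {
  h <- d@bandwidth
  mean(pnorm((d@support[2L] - centers) / h) -
       pnorm((d@support[1L] - centers) / h)) * 3
}

.kernelPdf <- function(d, x) {
  h <- d@bandwidth
  centers <- .kernelCenters(d)
  Z <- .kernelMass(d, centers)
  vapply(x, function(xx) 3 * mean(dnorm((xx - centers) / h)) / (h * Z),
         numeric(1L))
}

.kernelCdf <- function(d, x) {
  h <- d@bandwidth
  centers <- .kernelCenters(d)
  Z <- .kernelMass(d, centers)
  lowTail <- mean(pnorm((d@support[1L] - centers) / h))
  v <- vapply(x, function(xx)
    3 * (mean(pnorm((xx - centers) / h)) - lowTail) / Z, numeric(1L))
  pmin(pmax(v, 0), 1)
}
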