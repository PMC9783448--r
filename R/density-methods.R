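## pdf/cdf evaluation, quantile inversion, and the functional transforms.

.splinePdf <- function(d, x) {
  drop(cppSplinePdf(d@knots, d@coefficients, d@logNormConst, x))
}

.splineCdf <- function(d, x) {
  setup <- .splineSetup(length(d@coefficients), d@support)
  drop(cppSplineCdf(d@knots, d@coefficients, d@logNormConst, x,
                    setup$cdfGL$nodes, setup$cdfGL$weights))
}

#' Evaluate a density estimate
#'
#' @param d a [DensityEstimate-class].
#' @param points evaluation points, all inside the support.
#' @param mode `"pdf"` or `"cdf"`.
#' @return numeric vector of the same length as `points`.
#' @export
evaluateDensity <- function(d, points, mode = c("pdf", "cdf")) {
  mode <- match.arg(mode)
  if (any(points < d@support[1L] - 1e-12 | points > d@support[2L] + 1e-12))
    stop(sprintf("evaluation point outside the support [%g, %g]",
                 d@support[1L], d@support[2L]))
  points <- pmin(pmax(points, d@support[1L]), d@support[2L])
  if (d@method == "spline") {
    if (mode == "pdf") .splinePdf(d, points) else .splineCdf(d, points)
  } else {
    if (mode == "pdf") .kernelPdf(d, points) else .kernelCdf(d, points)
  }
}

#' Invert the cdf of a density estimate
#'
#' Monotone inversion by bisection to an absolute tolerance of 1e-8 in the
#' quantile value.  Levels must lie strictly inside (0, 1): the inverse at the
#' endpoints is the support boundary, excluded by convention.
#'
#' @param d a [DensityEstimate-class].
#' @param q quantile levels, all strictly inside (0, 1).
#' @return numeric vector, nondecreasing in `q`.
#' @export
invertCdf <- function(d, q) {
  if (any(q <= 0 | q >= 1))
    stop("quantile levels must lie strictly inside (0, 1)")
  if (d@method == "spline") {
    setup <- .splineSetup(length(d@coefficients), d@support)
    out <- drop(cppSplineQuantile(d@knots, d@coefficients, d@logNormConst, q,
                                  setup$cdfGL$nodes, setup$cdfGL$weights,
                                  1e-8))
    ## bisection noise (~1e-8) can locally invert an ordered grid; restore
    ## exact monotonicity for sorted levels
    if (!is.unsorted(q)) out <- cummax(out)
    return(out)
  }
  lo <- rep(d@support[1L], length(q))
  hi <- rep(d@support[2L], length(q))
  for (i in seq_len(ceiling(log2(diff(d@support) / 1e-8)) + 1L)) {
    mid <- (lo + hi) / 2
    below <- evaluateDensity(d, mid, "cdf") < q
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Midpoint quantile grid
#'
#' `m` evenly spaced quantile levels (j - 0.5)/m, j = 1..m.  Midpoints keep
#' the grid strictly inside (0, 1), where the quantile transforms are finite.
#'
#' @param m number of levels (default 101).
#' @return numeric vector of levels.
#' @export
quantileGrid <- function(m = 101L) (seq_len(m) - 0.5) / m

#' Apply a functional transform to a density estimate
#'
#' The transforms of the density-regression model: `identity` and `log`
#' evaluate f or log f on a support grid; `quantile` evaluates the quantile
#' function F^-1 on a quantile-level grid; `log_density_quantile` evaluates
#' the log density quantile log f(F^-1(q)), the quantile-synchronized
#' curve equal to -log dF^-1/dq.
#'
#' Kernel-method densities can underflow to zero in the tails; such pdf
#' values are floored at 1e-12 before taking logs (with a warning), keeping
#' the output finite.  Spline-form densities are strictly positive.
#'
#' @param d a [DensityEstimate-class].
#' @param kind one of `"identity"`, `"log"`, `"quantile"`,
#'   `"log_density_quantile"`.
#' @param grid quantile levels in (0, 1) for the quantile-indexed kinds
#'   (default [quantileGrid()]), support points otherwise (default an evenly
#'   spaced interior grid).
#' @return a [FunctionSample-class].
#' @examples
#' fs <- applyTransform(uniformDensity(), "log_density_quantile")
#' all.equal(fs@values, rep(-log(2), 101))
#' @export
applyTransform <- function(d,
                           kind = c("identity", "log", "quantile",
                                    "log_density_quantile"),
                           grid = NULL) {
  kind <- match.arg(kind)
  floorLog <- function(f) {
    if (any(f < 1e-12)) {
      warning("density floored at 1e-12 before log (kernel tail underflow)")
      f <- pmax(f, 1e-12)
    }
    log(f)
  }
  if (kind %in% c("identity", "log")) {
    if (is.null(grid)) {
      eps <- 1e-6
      grid <- seq(d@support[1L] + eps, d@support[2L] - eps, length.out = 101L)
    }
    f <- evaluateDensity(d, grid, "pdf")
    vals <- if (kind == "identity") f else floorLog(f)
  } else {
    if (is.null(grid)) grid <- quantileGrid()
    if (any(grid <= 0 | grid >= 1))
      stop("quantile-indexed transforms need grid levels strictly in (0, 1)")
    xq <- invertCdf(d, grid)
    vals <- if (kind == "quantile") xq else floorLog(evaluateDensity(d, xq, "pdf"))
  }
  new("FunctionSample", grid = grid, values = vals,
      transform = if (kind == "quantile") "quantile" else
        if (kind == "identity") "identity" else
        if (kind == "log") "log" else "log_density_quantile",
      subjectId = character(0))
}

setMethod("show", "DensityEstimate", function(object) {
  cat(sprintf("DensityEstimate (%s) on [%g, %g], fitted to n = %d values\n",
              object@method, object@support[1L], object@support[2L],
              object@n))
  if (object@method == "spline")
    cat(sprintf("  %d B-spline coefficients, penalty weight %.4g\n",
                length(object@coefficients), object@lambda))
  else
    cat(sprintf("  Gaussian kernel, bandwidth %.4g\n", object@bandwidth))
})

setMethod("show", "FunctionSample", function(object) {
  cat(sprintf("FunctionSample (%s): %d grid points in [%g, %g]\n",
              object@transform, length(object@grid),
              min(object@grid), max(object@grid)))
})
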