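## Stimulation-induced connectivity: the post-fit localization diagnostic.

#' @importFrom stats approx setNames
NULL

#' Per-edge effect map for one subject
#'
#' Under the log-density-quantile model the functional linear predictor is a
#' quantile integral that, by the probability integral transform, equals the
#' edge average of `g(Q_st) * log f(F^-1(Q_st))` with `Q_st = F(C_st)`
#' computed through the subject's own fitted cdf.  Since F^-1(F(x)) = x,
#' the log-density factor is just `log f(C_st)`.  The coefficient function
#' is interpolated linearly on the fit grid (and extrapolated as constant
#' beyond the outermost quantile levels).
#'
#' @param fit a [DensityLogitFit-class] fitted with the
#'   log-density-quantile transform.
#' @param d the subject's [DensityEstimate-class].
#' @param C the subject's connectivity matrix.
#' @return p x p symmetric effect matrix with zero diagonal.
#' @export
edgeEffectMap <- function(fit, d, C) {
  if (fit@transform != "log_density_quantile")
    stop("effect maps are defined for the log-density-quantile transform")
  validateConnectivityMatrix(C)
  es <- vectorizeUpperTriangle(C)
  Q <- evaluateDensity(d, es@values, "cdf")
  gQ <- approx(fit@basis@grid, fit@g@values, xout = Q, rule = 2L)$y
  logf <- log(pmax(evaluateDensity(d, es@values, "pdf"), 1e-300))
  eff <- gQ * logf
  p <- nrow(C)
  M <- matrix(0, p, p)
  M[cbind(es@s, es@t)] <- eff
  M[cbind(es@t, es@s)] <- eff
  M
}

#' Top-fraction selection frequency across subjects
#'
#' Per subject, marks the `ceiling(topFraction * E)` edges with the largest
#' absolute effect (E = p(p-1)/2; ties at the cutoff are all included) and
#' returns the per-edge selection rate across subjects.
#'
#' @param effects list of per-subject p x p effect matrices.
#' @param topFraction fraction of edges marked per subject, in (0, 1).
#' @return p x p symmetric frequency matrix with zero diagonal.
#' @export
consistencyFrequency <- function(effects, topFraction = 0.05) {
  if (length(effects) == 0L) stop("no effect maps supplied")
  if (topFraction <= 0 || topFraction >= 1)
    stop("topFraction must lie strictly in (0, 1)")
  p <- nrow(effects[[1L]])
  idx <- edgeIndex(p)
  E <- nrow(idx)
  k <- ceiling(topFraction * E)
  counts <- numeric(E)
  for (M in effects) {
    if (nrow(M) != p) stop("effect maps differ in dimension")
    a <- abs(M[cbind(idx$s, idx$t)])
    cutoff <- sort(a, decreasing = TRUE)[k]
    counts <- counts + (a >= cutoff)        # ties at the cutoff included
  }
  f <- counts / length(effects)
  FM <- matrix(0, p, p)
  FM[cbind(idx$s, idx$t)] <- f
  FM[cbind(idx$t, idx$s)] <- f
  FM
}

#' Induced connectivity across a study
#'
#' Averages the per-subject effect maps elementwise and computes the
#' top-fraction selection frequency of every region pair.
#'
#' @param effects list of per-subject p x p effect matrices.
#' @param topFraction fraction for the consistency selection (default 0.05).
#' @return an [InducedConnectivity-class].
#' @export
inducedConnectivity <- function(effects, topFraction = 0.05) {
  if (length(effects) == 0L) stop("no effect maps supplied")
  p <- nrow(effects[[1L]])
  avg <- Reduce(`+`, effects) / length(effects)
  new("InducedConnectivity", averageEffect = avg,
      frequency = consistencyFrequency(effects, topFraction),
      topFraction = topFraction, nSubjects = length(effects))
}

#' Induced connectivity directly from a fitted study
#'
#' Convenience wrapper: computes each subject's effect map from the fit,
#' the subject densities and the study matrices, then aggregates.
#'
#' @param fit a [DensityLogitFit-class] (log-density-quantile transform).
#' @param densities list of per-subject [DensityEstimate-class].
#' @param study the [ConnectivityStudy-class] the fit came from.
#' @param topFraction fraction for the consistency selection.
#' @return an [InducedConnectivity-class].
#' @export
studyInducedConnectivity <- function(fit, densities, study,
                                     topFraction = 0.05) {
  effects <- lapply(seq_len(ncol(study)), function(i)
    edgeEffectMap(fit, densities[[i]], connectivityMatrix(study, i)))
  inducedConnectivity(effects, topFraction)
}

setMethod("show", "InducedConnectivity", function(object) {
  cat(sprintf(
    "InducedConnectivity: %d x %d regions, %d subjects, top %.0f%%\n",
    nrow(object@averageEffect), ncol(object@averageEffect),
    object@nSubjects, 100 * object@topFraction))
  f <- object@frequency
  cat(sprintf("  max |average effect| %.4g, max selection frequency %.2f\n",
              max(abs(object@averageEffect)), max(f)))
})

#' Heatmap of an induced-connectivity matrix
#'
#' Minimal image-based rendering of the average-effect or frequency matrix.
#'
#' @param x an [InducedConnectivity-class].
#' @param which `"effect"` or `"frequency"`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plotInduced <- function(x, which = c("effect", "frequency"), ...) {
  which <- match.arg(which)
  M <- if (which == "effect") x@averageEffect else x@frequency
  p <- nrow(M)
  graphics::image(seq_len(p), seq_len(p), t(M[p:1, , drop = FALSE]),
                  xlab = "region", ylab = "region",
                  main = if (which == "effect") "average induced effect"
                  else "top-fraction selection frequency", ...)
  invisible(M)
}
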