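## Hyperparameter sensitivity: rescale each subject's default smoothing
## (spline penalty weight or kernel bandwidth) and track the LRT.

#' Sensitivity sweep over density-estimation hyperparameters
#'
#' Refits the whole density-regression pipeline with every subject's
#' smoothing hyperparameter scaled by each factor relative to its default
#' (the automatically selected spline penalty weight, or the Silverman
#' kernel bandwidth), and reports the likelihood-ratio p-value of the
#' functional term in each setting.  The default factor range covers
#' one-half to twice the default value.
#'
#' @param study a [ConnectivityStudy-class].
#' @param kind transform kind, default log density quantile.
#' @param methods density estimators to sweep, subset of
#'   `c("spline", "kernel")`.
#' @param factors multipliers applied to the default hyperparameter.
#' @param grid shared quantile grid.
#' @param varianceThreshold,smoothCovariance fPCA settings.
#' @return data.frame with columns method, factor, p, statistic, df.
#' @export
sensitivitySweep <- function(study, kind = "log_density_quantile",
                             methods = c("spline", "kernel"),
                             factors = c(0.5, 1 / sqrt(2), 1, sqrt(2), 2),
                             grid = quantileGrid(),
                             varianceThreshold = 0.99,
                             smoothCovariance = TRUE) {
  methods <- match.arg(methods, c("spline", "kernel"), several.ok = TRUE)
  edges <- assay(study, "edges")
  n <- ncol(edges)
  ## per-subject default hyperparameters
  theta0 <- list()
  if ("spline" %in% methods)
    theta0$spline <- vapply(seq_len(n), function(i)
      fitSplineDensity(edges[, i])@lambda, numeric(1L))
  if ("kernel" %in% methods)
    theta0$kernel <- vapply(seq_len(n), function(i)
      fitKernelDensity(edges[, i])@bandwidth, numeric(1L))
  rows <- list()
  for (m in methods) {
    for (f in factors) {
      dens <- lapply(seq_len(n), function(i) {
        if (m == "spline")
          fitSplineDensity(edges[, i], smoothing = theta0$spline[i] * f)
        else
          fitKernelDensity(edges[, i], bandwidth = theta0$kernel[i] * f)
      })
      samples <- suppressWarnings(buildFunctionalCovariates(dens, kind, grid))
      basis <- fitFPCA(samples, varianceThreshold, smoothCovariance)
      fit <- suppressWarnings(fitDensityLogit(study, basis, samples))
      lrt <- lrtVsBaseline(fit, study)
      rows[[length(rows) + 1L]] <-
        data.frame(method = m, factor = f, p = lrt$p,
                   statistic = lrt$statistic, df = lrt$df)
    }
  }
  do.call(rbind, rows)
}
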