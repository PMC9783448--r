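## Positive-finding-rate benchmark comparing edgewise, PC and density
## regression (all transforms) over replicated simulated studies.

.benchmarkMethods <- c("edgewise", "pc", "density_identity", "density_log",
                       "density_quantile", "density_ldq")

.transformOf <- c(density_identity = "identity", density_log = "log",
                  density_quantile = "quantile",
                  density_ldq = "log_density_quantile")

#' Run the stimulation benchmark
#'
#' Simulates `config@nReps` independent studies and records, per replicate
#' and method, whether the method declares any significant effect at level
#' `config@alpha`: the edgewise scan and PC regression by their
#' Bonferroni-corrected familywise flag, the density methods by the
#' likelihood-ratio test against the baseline-only model (the permutation
#' test is available separately but too costly inside a large replicate
#' loop).  Density fits are shared across the requested transforms.
#' Per-replicate seeds derive deterministically from the master seed, so
#' the decision matrix is reproducible replicate by replicate.
#'
#' @param config a [SimulationConfig-class].
#' @param methods subset of `c("edgewise", "pc", "density_identity",
#'   "density_log", "density_quantile", "density_ldq")`.
#' @param seed master seed (defaults to the config seed).
#' @param varianceThreshold,smoothCovariance fPCA settings for the density
#'   methods.
#' @return a [BenchmarkResult-class].
#' @export
runBenchmark <- function(config = simulationConfig(),
                         methods = .benchmarkMethods,
                         seed = config@seed,
                         varianceThreshold = 0.99,
                         smoothCovariance = TRUE) {
  methods <- match.arg(methods, .benchmarkMethods, several.ok = TRUE)
  decisions <- matrix(NA, nrow = config@nReps, ncol = length(methods),
                      dimnames = list(NULL, methods))
  densityKinds <- intersect(methods, names(.transformOf))
  grid <- quantileGrid()
  supportGrid <- seq(-1 + 1e-6, 1 - 1e-6, length.out = 101L)
  nFailed <- 0L
  for (r in seq_len(config@nReps)) {
    repSeed <- .deriveSeed(seed, r)
    res <- tryCatch({
      study <- simulateStudy(config, seed = repSeed)
      out <- setNames(logical(length(methods)), methods)
      if ("edgewise" %in% methods)
        out["edgewise"] <- edgewiseScan(study, alpha = config@alpha)@anyPositive
      if ("pc" %in% methods)
        out["pc"] <- suppressWarnings(
          pcRegression(study, alpha = config@alpha))@anyPositive
      if (length(densityKinds) > 0L) {
        dens <- lapply(seq_len(ncol(study)), function(i)
          fitSplineDensity(assay(study, "edges")[, i]))
        for (mk in densityKinds) {
          kind <- .transformOf[[mk]]
          g <- if (kind %in% c("identity", "log")) supportGrid else grid
          samples <- buildFunctionalCovariates(dens, kind, g)
          basis <- fitFPCA(samples, varianceThreshold, smoothCovariance)
          fit <- suppressWarnings(fitDensityLogit(study, basis, samples))
          out[mk] <- lrtVsBaseline(fit, study)$p <= config@alpha
        }
      }
      out
    }, error = function(e) NULL)
    if (is.null(res)) nFailed <- nFailed + 1L else decisions[r, ] <- res
  }
  ok <- !apply(decisions, 1L, anyNA)
  decisions <- decisions[ok, , drop = FALSE]
  rates <- colMeans(decisions)
  nReps <- nrow(decisions)
  new("BenchmarkResult", decisions = decisions, rates = rates,
      se = sqrt(rates * (1 - rates) / nReps), nReps = as.integer(nReps),
      nFailed = nFailed, config = config)
}

setMethod("show", "BenchmarkResult", function(object) {
  cat(sprintf("BenchmarkResult: scenario '%s', %d replicates%s\n",
              object@config@scenario, object@nReps,
              if (object@nFailed > 0L)
                sprintf(" (%d failed, excluded)", object@nFailed) else ""))
  for (m in names(object@rates))
    cat(sprintf("  %-18s rate %.3f (se %.3f)\n", m, object@rates[m],
                object@se[m]))
})

#' Benchmark rates as a data.frame
#'
#' @param result a [BenchmarkResult-class].
#' @return data.frame with columns method, rate, se, nReps.
#' @export
benchmarkRates <- function(result) {
  data.frame(method = names(result@rates), rate = unname(result@rates),
             se = unname(result@se), nReps = result@nReps,
             row.names = NULL)
}
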