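## The stimulation simulator: subject-level von Mises angle maps, cosine
## connectivity, and the convex-combination stimulation perturbation.

#' Construct a simulation configuration
#'
#' Named-argument constructor over [SimulationConfig-class]; unspecified
#' fields keep the benchmark defaults (20 regions, 50 subjects, half
#' stimulated, phi = pi, w = 0.75, non-localized scenario).
#'
#' @param ... slot values to override.
#' @return a validated [SimulationConfig-class].
#' @examples
#' simulationConfig(scenario = "null", nReps = 200L)
#' @export
simulationConfig <- function(...) {
  args <- list(...)
  obj <- new("SimulationConfig")
  for (nm in names(args)) {
    value <- args[[nm]]
    if (is(slot(obj, nm), "integer")) value <- as.integer(value)
    slot(obj, nm) <- value
  }
  validObject(obj)
  obj
}

#' Generate one subject's angle map and connectivity matrix
#'
#' Draws the upper-triangle angles i.i.d. from a von Mises law, sets the
#' connectivity to the cosine of each angle, symmetrizes, and puts ones on
#' the diagonal.
#'
#' @param params a [VonMisesParams-class].
#' @param p number of regions (at least 3).
#' @param seed optional RNG seed.
#' @return list with `theta` (p x p symmetric angle matrix, zero diagonal)
#'   and `C` (the connectivity matrix).
#' @export
generateSubject <- function(params, p, seed = NULL) {
  if (p < 3L) stop("need at least 3 regions")
  m <- p * (p - 1L) / 2L
  ang <- rVonMises(m, params, seed = seed)
  idx <- edgeIndex(p)
  theta <- matrix(0, p, p)
  theta[cbind(idx$s, idx$t)] <- ang
  theta[cbind(idx$t, idx$s)] <- ang
  C <- cos(theta)
  diag(C) <- 1
  list(theta = theta, C = C)
}

#' Apply the stimulation perturbation to one region
#'
#' Edges not touching the stimulated region are untouched (bit-identical).
#' Each edge (i0, j) becomes the convex combination
#' `w * C_ij + (1 - w) * cos(theta_ij + phi)`, computed in the incremental
#' form `C + (1 - w) * (cos(theta + phi) - C)` with the angle-addition
#' identity and `cospi`/`sinpi` for the rotation, so that exact rotations
#' (phi a multiple of pi) stay exact in floating point: at phi = pi the
#' stimulated edges equal (2w - 1) * C_ij bit-for-bit.
#'
#' @param theta p x p symmetric angle matrix (as from [generateSubject()]).
#' @param C the pre-stimulation connectivity matrix.
#' @param i0 stimulated region index.
#' @param w convex-combination weight in [0, 1] on the pre-stimulation edge.
#' @param phi rotation angle in radians.
#' @return the post-stimulation connectivity matrix (symmetric, unit
#'   diagonal).
#' @export
applyStimulation <- function(theta, C, i0, w, phi) {
  p <- nrow(C)
  if (i0 < 1L || i0 > p) stop("i0 must index a region")
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  others <- setdiff(seq_len(p), i0)
  cphi <- cospi(phi / pi)
  sphi <- sinpi(phi / pi)
  th <- theta[i0, others]
  rotated <- cos(th) * cphi - sin(th) * sphi
  Cst <- C
  ## incremental form: exact no-op at w = 1, exact scaling at phi = pi
  Cst[i0, others] <- C[i0, others] + (1 - w) * (rotated - C[i0, others])
  Cst[others, i0] <- Cst[i0, others]
  Cst
}

#' Simulate a full study
#'
#' Per subject, draws (mu, kappa) from the configured subject prior (wrapped
#' normal mean direction, log-normal concentration), generates a
#' connectivity map, and applies the stimulation to a randomly chosen half
#' of the subjects (exactly `stimulatedFraction * nSubjects` of them,
#' sampled without replacement).  The stimulated region is drawn uniformly
#' per subject in the non-localized scenario, fixed at `localizedRegion` in
#' the localized scenario, and no stimulation happens under the null.  The
#' treatment label A marks the stimulated subjects; the baseline design is
#' intercept-only.
#'
#' @param config a [SimulationConfig-class].
#' @param seed RNG seed (defaults to the config seed).
#' @return a [ConnectivityStudy-class]; `colData` records per-subject `A`
#'   and the stimulated region (NA for controls).
#' @export
simulateStudy <- function(config = simulationConfig(), seed = config@seed) {
  validObject(config)
  n <- config@nSubjects
  p <- config@nRegions
  nStim <- as.integer(round(config@stimulatedFraction * n))
  .withSeed(seed, {
    stimulated <- sort(sample.int(n, nStim))
    mats <- vector("list", n)
    stimRegion <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      mu <- .wrapAngle(rnorm(1L, config@muCenter, config@muSpread))
      kappa <- exp(rnorm(1L, config@kappaLogMean, config@kappaLogSd))
      subj <- generateSubject(vonMisesParams(mu, kappa), p)
      Ci <- subj$C
      if (config@scenario != "null" && i %in% stimulated) {
        i0 <- if (config@scenario == "localized") config@localizedRegion
        else sample.int(p, 1L)
        Ci <- applyStimulation(subj$theta, Ci, i0, config@w, config@phi)
        stimRegion[i] <- i0
      }
      mats[[i]] <- Ci
    }
    names(mats) <- sprintf("S%03d", seq_len(n))
    covar <- data.frame(
      A = as.integer(seq_len(n) %in% stimulated),
      intercept = 1,
      stimulatedRegion = stimRegion)
    ConnectivityStudy(mats, covar)
  })
}
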