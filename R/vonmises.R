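## Circular machinery for the stimulation benchmark: von Mises density,
## sampling (Best-Fisher rejection) and maximum-likelihood fitting via the
## Bessel-ratio equation.

#' @importFrom stats rbeta
NULL

#' Construct von Mises parameters
#'
#' @param mu mean direction in radians; wrapped to [-pi, pi).
#' @param kappa nonnegative concentration.
#' @return a [VonMisesParams-class].
#' @export
vonMisesParams <- function(mu, kappa) {
  new("VonMisesParams", mu = .wrapAngle(mu), kappa = kappa)
}

## wrap angles into [-pi, pi)
.wrapAngle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out >= pi] <- -pi
  out
}

#' von Mises density
#'
#' exp(kappa * cos(theta - mu)) / (2 * pi * I0(kappa)), the circular normal
#' law; kappa = 0 gives the uniform density 1 / (2 * pi).  Computed with the
#' exponentially scaled Bessel function for numerical stability at large
#' kappa.
#'
#' @param theta angles in radians.
#' @param params a [VonMisesParams-class] (or `mu`/`kappa` given directly).
#' @param mu,kappa alternative scalar parameterization.
#' @return density values.
#' @export
dVonMises <- function(theta, params = NULL, mu = NULL, kappa = NULL) {
  if (!is.null(params)) { mu <- params@mu; kappa <- params@kappa }
  if (kappa < 0) stop("kappa must be nonnegative")
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher wrapped-Cauchy rejection sampling; kappa = 0 falls back to
#' the uniform circle.  With a fixed `seed` the draw is bit-reproducible and
#' the caller's RNG state is untouched.
#'
#' @param n number of draws.
#' @param params a [VonMisesParams-class] (or `mu`/`kappa` given directly).
#' @param mu,kappa alternative scalar parameterization.
#' @param seed optional RNG seed.
#' @return n angles in [-pi, pi).
#' @export
rVonMises <- function(n, params = NULL, mu = NULL, kappa = NULL,
                      seed = NULL) {
  if (!is.null(params)) { mu <- params@mu; kappa <- params@kappa }
  if (kappa < 0) stop("kappa must be nonnegative")
  .withSeed(seed, {
    if (kappa < 1e-12) return(.wrapAngle(runif(n, -pi, pi)))
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    out <- numeric(n)
    got <- 0L
    while (got < n) {
      todo <- n - got
      u1 <- runif(todo); u2 <- runif(todo); u3 <- runif(todo)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      nok <- sum(ok)
      if (nok > 0L) {
        theta <- sign(u3[ok] - 0.5) * acos(f[ok]) + mu
        out[(got + 1L):(got + nok)] <- theta
        got <- got + nok
      }
    }
    .wrapAngle(out)
  })
}

## Bessel ratio A1(kappa) = I1/I0, computed with scaled Bessel functions
.besselRatio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

#' Maximum-likelihood von Mises fit
#'
#' The MLE of the mean direction is the circular mean; the concentration
#' solves A1(kappa) = I1(kappa)/I0(kappa) = Rbar (the mean resultant
#' length), found by Newton iteration from the Best-Fisher starting value
#' to a tolerance of 1e-10.
#'
#' @param angles numeric vector of angles (radians), at least 10 values.
#' @return a [VonMisesParams-class].
#' @export
fitVonMisesMLE <- function(angles) {
  n <- length(angles)
  if (n < 10L) stop("need at least 10 angles")
  if (max(angles) - min(angles) < 1e-14)
    stop("degenerate sample: all angles identical")
  C <- mean(cos(angles)); S <- mean(sin(angles))
  Rbar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C)
  if (Rbar >= 1 - 1e-12)
    stop("degenerate concentration: mean resultant length is 1")
  if (Rbar < 1e-12) return(vonMisesParams(mu, 0))
  ## Best-Fisher starting value
  k <- if (Rbar < 0.53) 2 * Rbar + Rbar^3 + 5 * Rbar^5 / 6
  else if (Rbar < 0.85) -0.4 + 1.39 * Rbar + 0.43 / (1 - Rbar)
  else 1 / (Rbar^3 - 4 * Rbar^2 + 3 * Rbar)
  for (it in seq_len(100L)) {
    A <- .besselRatio(k)
    ## A'(kappa) = 1 - A/kappa - A^2
    step <- (A - Rbar) / (1 - A / k - A^2)
    kNew <- max(k - step, k / 10)
    if (abs(kNew - k) < 1e-10) { k <- kNew; break }
    k <- kNew
  }
  vonMisesParams(mu, k)
}

#' von Mises log-likelihood of a sample
#'
#' @param angles numeric angles.
#' @param params a [VonMisesParams-class].
#' @return total log-likelihood.
#' @export
vonMisesLogLik <- function(angles, params) {
  sum(log(dVonMises(angles, params)))
}

setMethod("show", "VonMisesParams", function(object) {
  cat(sprintf("VonMisesParams: mu = %.4f rad, kappa = %.4f\n",
              object@mu, object@kappa))
})
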