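## Internal numerical helpers shared across modules.

#' @importFrom stats dnorm pnorm qnorm rnorm runif integrate optim
#' @importFrom methods new validObject is slot slotNames
NULL

## Trapezoid quadrature weights for an arbitrary strictly increasing grid.
.trapzWeights <- function(grid) {
  m <- length(grid)
  if (m < 2L) stop("grid must have at least two points")
  d <- diff(grid)
  w <- numeric(m)
  w[1L] <- d[1L] / 2
  w[m] <- d[m - 1L] / 2
  if (m > 2L) w[2:(m - 1L)] <- (d[-(m - 1L)] + d[-1L]) / 2
  w
}

.trapz <- function(grid, values) sum(.trapzWeights(grid) * values)

## Quadrature weights for a function grid.  Midpoint-constructed grids
## (uniform spacing h with the first point at h/2 from 0 and the last at
## h/2 from 1, as quantile-level grids are) get midpoint-rule weights,
## which carry unit total mass over [0, 1]; any other grid gets the
## trapezoid rule on its own span.
.quadWeights <- function(grid) {
  m <- length(grid)
  h <- diff(grid)
  if (m >= 2L && max(h) - min(h) < 1e-12 &&
      abs(grid[1L] - h[1L] / 2) < 1e-9 &&
      abs(1 - grid[m] - h[1L] / 2) < 1e-9)
    return(rep(h[1L], m))
  .trapzWeights(grid)
}

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
.gaussLegendre <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * (e$vectors[1L, ord])^2)
}

## Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic per-replicate seed stream below 2^31.
.deriveSeed <- function(master, i) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(i)) %% 2147483647)
}

## Area under the ROC curve by the rank (Wilcoxon) formula; ties get midranks.
.rankAUC <- function(scores, labels) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.isWholeNumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol
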