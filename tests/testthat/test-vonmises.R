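test_that("the von Mises density is a proper circular density", {
  expect_equal(dVonMises(seq(-pi, pi, 0.5), mu = 0, kappa = 0),
               rep(1 / (2 * pi), 13), tolerance = 1e-12)
  for (k in c(0.5, 2, 10)) {
    expect_equal(integrate(function(t) dVonMises(t, mu = 0.7, kappa = k),
                           -pi, pi, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-8)
    grid <- seq(-pi, pi, length.out = 2001L)
    expect_true(all(dVonMises(0.7, mu = 0.7, kappa = k) >=
                      dVonMises(grid, mu = 0.7, kappa = k)))
  }
})

test_that("sampling matches the target law and is reproducible", {
  th0 <- rVonMises(1e5, mu = 0, kappa = 0, seed = 5)
  R <- sqrt(mean(cos(th0))^2 + mean(sin(th0))^2)
  expect_lte(R, 0.02)                    # uniform circle: E[R] ~ 1/sqrt(n)
  th2 <- rVonMises(1e5, mu = 1, kappa = 2, seed = 6)
  expect_equal(atan2(mean(sin(th2)), mean(cos(th2))), 1, tolerance = 0.02)
  expect_true(all(th2 >= -pi & th2 < pi))
  expect_identical(rVonMises(100, mu = 1, kappa = 2, seed = 7),
                   rVonMises(100, mu = 1, kappa = 2, seed = 7))
})

test_that("the MLE matches a grid-search likelihood oracle", {
  th <- rVonMises(1e4, mu = 1, kappa = 2, seed = 99)
  fit <- fitVonMisesMLE(th)
  expect_lt(abs(fit@mu - 1), 0.05)
  expect_lt(abs(fit@kappa - 2), 0.15)
  ## oracle: exact log-likelihood on a lattice via sufficient statistics
  Sc <- sum(cos(th)); Ss <- sum(sin(th)); n <- length(th)
  ll <- function(mu, k)
    k * (cos(mu) * Sc + sin(mu) * Ss) - n * log(2 * pi * besselI(k, 0))
  mus <- seq(0.8, 1.2, by = 0.005)
  ks <- seq(1.6, 2.4, by = 0.005)
  lat <- outer(mus, ks, Vectorize(ll))
  best <- which(lat == max(lat), arr.ind = TRUE)[1L, ]
  expect_lt(abs(fit@mu - mus[best[1L]]), 0.01)
  expect_lt(abs(fit@kappa - ks[best[2L]]), 0.01)
  ## optimality: the MLE log-likelihood dominates every lattice point
  expect_gte(ll(fit@mu, fit@kappa), max(lat))
})

test_that("uniform samples give near-zero concentration", {
  th <- rVonMises(1e4, mu = 0, kappa = 0, seed = 17)
  expect_lte(fitVonMisesMLE(th)@kappa, 0.05)
})

test_that("estimation error shrinks like 1/sqrt(n)", {
  rmse <- vapply(c(1e2, 1e3, 1e4), function(n) {
    errs <- vapply(1:30, function(r) {
      th <- rVonMises(n, mu = 1, kappa = 2, seed = 700 * n + r)
      f <- fitVonMisesMLE(th)
      (f@kappa - 2)^2 + (f@mu - 1)^2
    }, numeric(1L))
    sqrt(mean(errs))
  }, numeric(1L))
  expect_true(all(diff(rmse) < 0))
  ## an order of magnitude in n buys roughly sqrt(10) in RMSE
  expect_lt(rmse[3L], rmse[1L] / 4)
})

test_that("degenerate inputs are rejected", {
  expect_error(fitVonMisesMLE(rep(0.5, 100)), "identical")
  expect_error(fitVonMisesMLE(runif(5)), "at least 10")
  expect_error(rVonMises(10, mu = 0, kappa = -1), "nonnegative")
})
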