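test_that("log-spline fit recovers closed-form densities", {
  set.seed(42)
  x <- runif(5000, -1, 1)
  d <- fitSplineDensity(x)
  grid <- seq(-1, 1, length.out = 201L)
  expect_lt(max(abs(evaluateDensity(d, grid, "pdf") - 0.5)), 0.05)

  set.seed(7)
  b <- 2 * rbeta(5000, 5, 5) - 1
  db <- fitSplineDensity(b)
  gg <- seq(-1 + 1e-6, 1 - 1e-6, length.out = 2001L)
  err <- abs(evaluateDensity(db, gg, "pdf") - dbeta((gg + 1) / 2, 5, 5) / 2)
  L1 <- sum(diff(gg) * (err[-1L] + err[-length(err)]) / 2)
  expect_lt(L1, 0.08)
})

test_that("every fit integrates to one and has a proper cdf", {
  set.seed(5)
  for (x in list(runif(200, -1, 1), cos(rnorm(190, 1.2, 0.8)),
                 2 * rbeta(1000, 2, 6) - 1)) {
    d <- fitSplineDensity(x)
    expect_equal(integrate(function(t) evaluateDensity(d, t, "pdf"),
                           -1, 1, rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
    expect_equal(evaluateDensity(d, -1, "cdf"), 0, tolerance = 1e-6)
    expect_equal(evaluateDensity(d, 1, "cdf"), 1, tolerance = 1e-6)
    cdf <- evaluateDensity(d, seq(-0.99, 0.99, length.out = 50L), "cdf")
    expect_true(all(diff(cdf) > 0))
  }
})

test_that("cdf/quantile round trips hold on a 99-point lattice", {
  set.seed(11)
  d <- fitSplineDensity(cos(rnorm(500, 1.2, 0.8)))
  q <- (1:99) / 100
  xq <- invertCdf(d, q)
  expect_false(is.unsorted(xq))
  expect_lt(max(abs(evaluateDensity(d, xq, "cdf") - q)), 1e-6)
  ## median of a symmetric sample sits near zero
  set.seed(12)
  ds <- fitSplineDensity(runif(2000, -1, 1))
  expect_lt(abs(invertCdf(ds, 0.5)), 0.05)
  expect_equal(invertCdf(ds, 0.75), 0.5, tolerance = 0.05)
  expect_equal(evaluateDensity(ds, 0, "cdf"), 0.5, tolerance = 0.02)
  expect_error(invertCdf(d, c(0, 0.5)), "strictly inside")
})

test_that("degenerate and misconfigured inputs are rejected", {
  expect_error(fitSplineDensity(rep(0.3, 100)), "distinct")
  expect_error(fitSplineDensity(runif(100, -1, 1), degreesOfFreedom = 3),
               "at least 4")
  expect_error(fitSplineDensity(runif(100), smoothing = -1), "nonnegative")
  d <- fitSplineDensity(runif(100, -1, 1))
  expect_error(evaluateDensity(d, 1.5, "pdf"), "outside the support")
})

test_that("fits are bit-identical under region relabeling", {
  C <- generateSubject(vonMisesParams(1.2, 1.5), 12, seed = 9)$C
  perm <- sample(seq_len(12))
  d1 <- fitSplineDensity(vectorizeUpperTriangle(C))
  d2 <- fitSplineDensity(vectorizeUpperTriangle(relabelRegions(C, perm)))
  expect_identical(d1@coefficients, d2@coefficients)
  expect_identical(d1@lambda, d2@lambda)
  expect_identical(d1@logNormConst, d2@logNormConst)
})

test_that("a fixed smoothing weight is honored and still normalized", {
  set.seed(13)
  x <- cos(rnorm(190, 1.2, 0.8))
  auto <- fitSplineDensity(x)
  for (f in c(0.5, 2)) {
    d <- fitSplineDensity(x, smoothing = auto@lambda * f)
    expect_equal(d@lambda, auto@lambda * f)
    expect_equal(integrate(function(t) evaluateDensity(d, t, "pdf"),
                           -1, 1)$value, 1, tolerance = 1e-6)
  }
})
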