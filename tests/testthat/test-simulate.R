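test_that("generated subjects are valid cosine-connectivity maps", {
  sub <- generateSubject(vonMisesParams(1.2, 1.5), 20, seed = 3)
  expect_silent(validateConnectivityMatrix(sub$C))
  expect_identical(sub$C, t(sub$C))
  expect_equal(diag(sub$C), rep(1, 20))
  expect_length(vectorizeUpperTriangle(sub$C)@values, 190L)
  ## high concentration at mu = 0 pushes edges toward cos(0) = 1
  tight <- generateSubject(vonMisesParams(0, 50), 20, seed = 4)
  expect_gte(mean(vectorizeUpperTriangle(tight$C)@values), 0.95)
})

test_that("stimulation algebra is exact", {
  sub <- generateSubject(vonMisesParams(1.2, 1.5), 20, seed = 5)
  others <- setdiff(1:20, 7)
  ## w = 1 is a bit-exact no-op
  expect_identical(applyStimulation(sub$theta, sub$C, 7, 1, pi), sub$C)
  ## phi = pi scales the stimulated row by exactly 2w - 1
  st <- applyStimulation(sub$theta, sub$C, 7, 0.75, pi)
  expect_identical(st[7, others], 0.5 * sub$C[7, others])
  expect_identical(st[others, 7], 0.5 * sub$C[others, 7])
  ## rows not touching the stimulated region are bit-identical
  expect_identical(st[others, others], sub$C[others, others])
  expect_identical(st, t(st))
  expect_equal(diag(st), rep(1, 20))
})

test_that("stimulation commutes with region relabeling", {
  sub <- generateSubject(vonMisesParams(0.8, 2), 12, seed = 6)
  perm <- withr::with_seed(7, sample(12L))
  i0 <- 4L
  a <- relabelRegions(applyStimulation(sub$theta, sub$C, i0, 0.75, pi), perm)
  thetaP <- relabelRegions(sub$theta, perm)
  CP <- relabelRegions(sub$C, perm)
  b <- applyStimulation(thetaP, CP, which(perm == i0), 0.75, pi)
  expect_identical(a, b)
})

test_that("simulated studies honor the stimulated-half design", {
  cfg <- simulationConfig(scenario = "nonlocalized")
  st <- simulateStudy(cfg, seed = 11)
  expect_identical(sum(treatmentLabels(st)), 25L)
  expect_identical(ncol(st), 50L)
  ## each treated subject has exactly one row rescaled; at phi = pi and
  ## w = 0.75 no other mechanism halves a full row
  cd <- SummarizedExperiment::colData(st)
  expect_true(all(!is.na(cd$stimulatedRegion[cd$A == 1])))
  expect_true(all(is.na(cd$stimulatedRegion[cd$A == 0])))
  ## reproducibility
  st2 <- simulateStudy(cfg, seed = 11)
  expect_identical(SummarizedExperiment::assay(st, "edges"),
                   SummarizedExperiment::assay(st2, "edges"))
  ## odd split rejected
  expect_error(validObject(simulationConfig(nSubjects = 49L)), "integer")
})

test_that("null-scenario arms are exchangeable", {
  ok <- vapply(1:400, function(r) {
    st <- simulateStudy(simulationConfig(scenario = "null", nSubjects = 30L),
                        seed = 20000 + r)
    E <- SummarizedExperiment::assay(st, "edges")
    A <- treatmentLabels(st)
    m <- colMeans(E)
    stats::t.test(m[A == 1], m[A == 0])$p.value > 0.05
  }, logical(1L))
  expect_gte(mean(ok), 0.93)
})

test_that("post-stimulation edges of the hit row scale by 2w - 1 in law", {
  ## closed form: at phi = pi the stimulated row's edge distribution is the
  ## pre-stimulation law scaled by (2w - 1); compare sample quantiles
  withr::with_seed(21, {
    prm <- vonMisesParams(1.0, 2)
    draws <- replicate(400, {
      sub <- generateSubject(prm, 10)
      st <- applyStimulation(sub$theta, sub$C, 3, 0.6, pi)
      c(pre = sub$C[3, 5], post = st[3, 5])
    })
    expect_equal(unname(draws["post", ] / draws["pre", ]),
                 rep(2 * 0.6 - 1, 400), tolerance = 1e-12)
  })
})

test_that("benchmark decisions are a deterministic function of the seed", {
  cfg <- simulationConfig(scenario = "nonlocalized", nReps = 4L)
  b1 <- runBenchmark(cfg, methods = c("edgewise", "pc"), seed = 9)
  b2 <- runBenchmark(cfg, methods = c("edgewise", "pc"), seed = 9)
  expect_identical(b1@decisions, b2@decisions)
  expect_identical(b1@nFailed, 0L)
  expect_equal(b1@rates, colMeans(b1@decisions))
  expect_equal(b1@se, sqrt(b1@rates * (1 - b1@rates) / b1@nReps))
  df <- benchmarkRates(b1)
  expect_identical(df$method, c("edgewise", "pc"))
})
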