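test_that("the 78-region scan tests exactly 3003 edges", {
  study <- makeStudyFixture(n = 16L, nTreated = 8L, p = 78L, seed = 51)
  ## intercept-only baseline keeps the per-edge fits well posed at n = 16
  cov <- data.frame(A = treatmentLabels(study), intercept = 1)
  study2 <- ConnectivityStudy(
    lapply(seq_len(16L), function(i) connectivityMatrix(study, i)), cov)
  res <- edgewiseScan(study2)
  expect_identical(res@familySize, 3003L)
  expect_length(res@pRaw, 3003L)
  expect_equal(res@pAdjusted, pmin(1, res@pRaw * 3003), tolerance = 1e-12)
})

test_that("a genuinely localized planted effect is found by the edge scan", {
  ## one edge shifted in the treated arm, all other edges exchangeable
  hits <- vapply(1:200, function(r) {
    withr::with_seed(52000 + r, {
      n <- 200L; p <- 8L
      A <- rep(0:1, each = n / 2)
      ## base angles centered at pi/2 keep edges near 0, so the planted
      ## +0.4 correlation shift is not flattened by the [-1, 1] clamp
      mats <- lapply(seq_len(n), function(i) {
        C <- generateSubject(vonMisesParams(pi / 2, 2), p)$C
        if (A[i] == 1L)
          C[2, 5] <- C[5, 2] <- max(min(C[2, 5] + 0.4, 1), -1)
        C
      })
      names(mats) <- sprintf("S%03d", seq_len(n))
      study <- ConnectivityStudy(mats, data.frame(A = A, intercept = 1))
      res <- edgewiseScan(study)
      res@pAdjusted[res@s == 2L & res@t == 5L] <= 0.05
    })
  }, logical(1L))
  expect_gte(mean(hits), 0.80)
})

test_that("PC regression recovers a rank-one planted perturbation", {
  withr::with_seed(53, {
    n <- 60L; p <- 10L
    A <- rep(0:1, each = n / 2)
    direction <- rnorm(p * (p - 1) / 2)
    direction <- direction / sqrt(sum(direction^2))
    idx <- edgeIndex(p)
    mats <- lapply(seq_len(n), function(i) {
      base <- 0.6 * tanh(rnorm(1) + 3 * A[i]) * direction +
        rnorm(length(direction), sd = 0.02)
      base <- pmin(pmax(base, -0.99), 0.99)
      M <- diag(p)
      M[cbind(idx$s, idx$t)] <- base
      M[cbind(idx$t, idx$s)] <- base
      M
    })
    names(mats) <- sprintf("S%03d", seq_len(n))
    study <- ConnectivityStudy(mats, data.frame(A = A, intercept = 1))
    res <- suppressWarnings(pcRegression(study))
    expect_identical(unname(which.min(res@pRaw)), 1L)
    ## PCA contract: score columns orthogonal
    G <- crossprod(res@scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  })
})

test_that("component counts are capped for identifiability", {
  study <- makeStudyFixture(n = 14L, nTreated = 7L, p = 12L, seed = 54)
  expect_warning(res <- pcRegression(study), "truncated")
  expect_lte(res@nComponents, 14L - ncol(designMatrix(study)) - 1L)
  expect_true(res@truncated)
  expect_error(pcRegression(study, varianceThreshold = 0), "in \\(0, 1\\]")
})
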