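test_that("log-likelihood matches the hand-evaluated closed form", {
  h <- detectionHistoryFromMatrix(matrix(c(1, 0, 1, 0), 2, 2))
  # n. = 1, n_1 = n_2 = 1: L = 0.5 * 0.25 * (0.5 * 0.25 + 0.5) = 0.078125
  expect_equal(occupancyLoglik(0.5, 0.5, h), log(0.078125), tolerance = 1e-12)
  expect_error(occupancyLoglik(1.2, 0.5, h), "strictly in")
  expect_error(occupancyLoglik(0.5, 0, h), "strictly in")
})

test_that("likelihood approaches 1 when everything is detected and psi, p -> 1", {
  h <- detectionHistoryFromMatrix(matrix(1L, 4, 3))
  lls <- vapply(c(1e-3, 1e-5, 1e-7),
                function(eps) occupancyLoglik(1 - eps, 1 - eps, h), numeric(1))
  expect_true(all(diff(lls) > 0))
  expect_lt(abs(lls[3]), 1e-5)
})

test_that("likelihood equals the brute-force latent-state enumeration", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      N <- sample(3:8, 1); Tocc <- sample(2:5, 1)
      m <- matrix(rbinom(N * Tocc, 1, 0.4), N, Tocc)
      if (rep > 5) {
        m[sample(N * Tocc, round(0.2 * N * Tocc))] <- NA  # missing effort
        for (i in which(rowSums(!is.na(m)) == 0)) m[i, 1] <- 0L
      }
      h <- detectionHistoryFromMatrix(m)
      psi <- runif(1, 0.1, 0.9)
      p <- runif(1, 0.1, 0.9)
      expect_equal(exp(occupancyLoglik(psi, p, h)),
                   bruteOccupancyLik(psi, p, m), tolerance = 1e-10)
      # time-varying p too
      pt <- runif(Tocc, 0.1, 0.9)
      expect_equal(exp(occupancyLoglik(psi, pt, h)),
                   bruteOccupancyLik(psi, pt, m), tolerance = 1e-10)
    }
  })
})

test_that("balanced histories reproduce the printed closed form exactly", {
  withr::with_seed(8, {
    for (rep in 1:5) {
      m <- matrix(rbinom(24, 1, 0.35), 6, 4)
      h <- detectionHistoryFromMatrix(m)
      psi <- runif(1, 0.2, 0.8); p <- runif(1, 0.2, 0.8)
      expect_equal(exp(occupancyLoglik(psi, p, h)),
                   closedFormOccupancyLik(psi, p, m), tolerance = 1e-10)
    }
  })
})

test_that("likelihood is invariant under site and occasion permutation", {
  withr::with_seed(3, {
    m <- matrix(rbinom(50, 1, 0.3), 10, 5)
  })
  h <- detectionHistoryFromMatrix(m)
  ll <- occupancyLoglik(0.6, 0.3, h)
  hs <- detectionHistoryFromMatrix(m[sample(10), ])
  ho <- detectionHistoryFromMatrix(m[, sample(5)])
  expect_equal(occupancyLoglik(0.6, 0.3, hs), ll)
  expect_equal(occupancyLoglik(0.6, 0.3, ho), ll)
})

test_that("the MLE matches the refined grid-search oracle on a fixed fixture", {
  sim <- simulateOccupancy(N = 20, T = 5, psi = 0.6, p = 0.4, seed = 20)
  h <- sim$history
  fit <- fitOccupancy(h)
  expect_false(fit@boundary)
  grid <- oracleGridFit(h, gridSize = 1000, refine = 2)
  expect_lt(abs(psiHat(fit) - grid["psi"]), 1e-4)
  expect_lt(abs(pHat(fit) - grid["p"]), 1e-4)
  # at the maximum, the oracle's own likelihood cannot beat the fit's
  expect_lte(occupancyLoglik(grid["psi"], grid["p"], h),
             fit@loglik + 1e-8)
})

test_that("grid refinement halves the maximum disagreement", {
  withr::with_seed(21, {
    m <- matrix(rbinom(60, 1, 0.3), 12, 5)
  })
  h <- detectionHistoryFromMatrix(m)
  fit <- fitOccupancy(h)
  err <- function(g) max(abs(c(g["psi"] - psiHat(fit), g["p"] - pHat(fit))))
  e0 <- err(oracleGridFit(h, 200))
  e1 <- err(oracleGridFit(h, 200, refine = 1))
  e2 <- err(oracleGridFit(h, 200, refine = 2))
  expect_lt(e1, e0 / 2 + 1e-12)
  expect_lt(e2, e1 / 2 + 1e-12)
})

test_that("boundary histories are flagged with unreliable SEs", {
  h <- detectionHistoryFromMatrix(matrix(1L, 5, 4))
  expect_warning(fit <- fitOccupancy(h), "boundary")
  expect_equal(psiHat(fit), 1)
  expect_equal(pHat(fit), 1)
  expect_true(fit@boundary)
  expect_true(is.na(fit@sePsi))

  h0 <- detectionHistoryFromMatrix(matrix(0L, 5, 4))
  expect_warning(fit0 <- fitOccupancy(h0), "boundary")
  expect_equal(psiHat(fit0), 0)
})

test_that("constant-p MLE satisfies its score equation and dominates naive", {
  withr::with_seed(31, {
    for (rep in 1:6) {
      sim <- simulateOccupancy(N = 80, T = 6, psi = runif(1, 0.3, 0.8),
                               p = runif(1, 0.2, 0.6), seed = 100 + rep)
      fit <- fitOccupancy(sim$history)
      if (fit@boundary) next
      N <- fit@nSites; Tocc <- fit@nOccasions
      ndot <- nDot(sim$history)
      # psi * (1 - (1-p)^T) * N = n. at the MLE
      expect_equal(psiHat(fit) * (1 - (1 - pHat(fit))^Tocc) * N, ndot,
                   tolerance = 1e-6)
      expect_gte(psiHat(fit), naiveOccupancy(fit) - 1e-8)
    }
  })
})

test_that("missing-at-random cells leave the fit consistent", {
  sim <- simulateOccupancy(N = 400, T = 8, psi = 0.6, p = 0.3,
                           missingFraction = 0.3, seed = 51)
  fit <- fitOccupancy(sim$history)
  expect_true(fit@converged)
  expect_lt(abs(psiHat(fit) - 0.6), 0.15)
  expect_lt(abs(pHat(fit) - 0.3), 0.1)
})

test_that("time-varying detection recovers an occasion effect", {
  # occasions alternate p = 0.2 and p = 0.5
  withr::with_seed(61, {
    N <- 600; Tocc <- 6
    z <- rbinom(N, 1, 0.7)
    pt <- rep(c(0.2, 0.5), 3)
    m <- sapply(pt, function(p) rbinom(N, 1, p)) * z
  })
  h <- detectionHistoryFromMatrix(m)
  fit <- fitOccupancy(h, pStructure = "time")
  expect_length(pHat(fit), Tocc)
  expect_lt(mean(abs(pHat(fit) - pt)), 0.05)
  expect_lt(abs(psiHat(fit) - 0.7), 0.07)
})

test_that("detection stratified by a binary covariate recovers both levels", {
  # two camera sensitivity classes with different p; fit each stratum
  withr::with_seed(71, {
    z <- rbinom(300, 1, 0.6)
    mLow <- matrix(rbinom(150 * 8, 1, 0.15), 150, 8) * z[1:150]
    mHigh <- matrix(rbinom(150 * 8, 1, 0.45), 150, 8) * z[151:300]
  })
  fLow <- fitOccupancy(detectionHistoryFromMatrix(mLow))
  fHigh <- fitOccupancy(detectionHistoryFromMatrix(mHigh))
  expect_lt(abs(pHat(fLow) - 0.15), 0.06)
  expect_lt(abs(pHat(fHigh) - 0.45), 0.06)
  expect_gt(pHat(fHigh), pHat(fLow))
})

test_that("standard errors are finite and plausibly scaled", {
  sim <- simulateOccupancy(N = 300, T = 8, psi = 0.6, p = 0.35, seed = 81)
  fit <- fitOccupancy(sim$history)
  expect_true(is.finite(fit@sePsi) && fit@sePsi > 0)
  expect_true(all(is.finite(fit@seP) & fit@seP > 0))
  expect_lt(fit@sePsi, 0.2)
  expect_lt(abs(psiHat(fit) - 0.6), 3 * fit@sePsi + 0.05)
})
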