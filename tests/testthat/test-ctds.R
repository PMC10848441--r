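# Detection functions, encounter rate, density, CV composition, bootstrap.

test_that("detection function is 1 at zero and errors beyond w", {
  f <- makeDetFit(PHat = 0.5, w = 10, sigma = 4)
  expect_equal(detectionG(0, f), 1)
  expect_error(detectionG(10.5, f), "within")
  x <- seq(0, 10, by = 0.5)
  g <- detectionG(x, f)
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(diff(g) <= 0))
})

test_that("half-normal average detection probability has its closed form", {
  # sigma = w: P = (2 sigma^2 / w^2)(1 - exp(-w^2 / 2 sigma^2)) = 2(1 - e^-0.5)
  w <- 10
  x <- sampleRadialDistances(400, function(x) exp(-x^2 / (2 * w^2)), w,
                             seed = 12)
  fit <- fitDetectionFunction(x, key = "half_normal", w = w, binned = FALSE)
  closed <- function(sigma) 2 * sigma^2 / w^2 * (1 - exp(-w^2 / (2 * sigma^2)))
  expect_equal(PHat(fit), closed(fit@sigma), tolerance = 1e-6)

  # and the closed-form constant at sigma = w exactly
  fixed <- makeDetFit(PHat = closed(w), w = w, sigma = w)
  quad <- stats::integrate(function(u) detectionG(u, fixed) * 2 * u / w^2,
                           0, w, rel.tol = 1e-10)$value
  expect_equal(quad, 2 * (1 - exp(-0.5)), tolerance = 1e-6)
  expect_equal(PHat(fixed), quad, tolerance = 1e-6)
})

test_that("P-hat matches adaptive quadrature for every key and adjustment", {
  w <- 10
  hr <- methods::new("DetectionFunctionFit", key = "hazard_rate", sigma = 5,
                     shape = 3, cosCoef = numeric(0), w = w, PHat = 0.5,
                     loglik = -1, aic = 6, nParams = 2L, nObs = 50L,
                     vcov = matrix(NA_real_, 2, 2), binned = FALSE)
  quad <- stats::integrate(function(u) detectionG(u, hr) * 2 * u / w^2,
                           0, w, rel.tol = 1e-10)$value
  # package quadrature route
  pkgP <- camsnap:::averageDetection("hazard_rate", 5, 3, numeric(0), w)
  expect_equal(pkgP, quad, tolerance = 1e-6)

  # a fitted model with adjustments agrees with quadrature of its own g
  x <- sampleRadialDistances(600, function(x) exp(-x^2 / (2 * 16)), w,
                             seed = 3)
  fit <- suppressWarnings(
    fitDetectionFunction(x, key = "half_normal", nAdjustments = 1, w = w,
                         binned = FALSE))
  quadFit <- stats::integrate(function(u) detectionG(u, fit) * 2 * u / w^2,
                              0, w, rel.tol = 1e-10)$value
  expect_equal(PHat(fit), quadFit, tolerance = 1e-6)
})

test_that("the half-normal scale is recovered from simulated distances", {
  w <- 10; sigma <- 4
  x <- sampleRadialDistances(2000, function(x) exp(-x^2 / (2 * sigma^2)), w,
                             seed = 3)
  fit <- fitDetectionFunction(x, key = "half_normal", w = w, binned = FALSE)
  expect_lt(abs(fit@sigma - sigma), 0.2)

  # binned (1 m bins) and exact fits agree on P
  fitB <- fitDetectionFunction(x, key = "half_normal", w = w, binned = TRUE)
  expect_lt(abs(PHat(fitB) - PHat(fit)), 0.02)

  # pre-binned counts interface gives the same fit as internal binning
  breaks <- 0:10
  counts <- as.numeric(table(cut(x, breaks, include.lowest = TRUE)))
  fitC <- fitDetectionFunction(counts = counts, breaks = breaks,
                               key = "half_normal")
  expect_equal(fitC@sigma, fitB@sigma, tolerance = 1e-6)
})

test_that("uniform detectability yields P-hat near 1", {
  w <- 10
  withr::with_seed(14, {
    x <- w * sqrt(stats::runif(1500))   # g == 1: pure 2x/w^2
  })
  fit <- fitDetectionFunction(x, key = "half_normal", w = w)
  expect_gte(PHat(fit), 0.95)
})

test_that("fits refuse fewer than 10 observations", {
  expect_error(fitDetectionFunction(c(1, 2, 3), key = "half_normal", w = 10),
               "fewer than 10")
})

test_that("P-hat decreases monotonically with sigma", {
  P <- vapply(c(1, 2, 4, 8),
              function(s) camsnap:::averageDetection("half_normal", s,
                                                     NA_real_, numeric(0), 10),
              numeric(1))
  expect_true(all(diff(P) > 0))
})

test_that("Akaike weights follow the hand-computed formula", {
  mkFit <- function(ll, k) {
    methods::new("DetectionFunctionFit", key = "half_normal", sigma = 4,
                 shape = NA_real_, cosCoef = numeric(0), w = 10, PHat = 0.5,
                 loglik = ll, aic = 2 * k - 2 * ll, nParams = as.integer(k),
                 nObs = 100L, vcov = matrix(NA_real_, 1, 1), binned = FALSE)
  }
  # single model
  avg1 <- suppressWarnings(modelAverage(list(mkFit(-100, 1))))
  expect_equal(akaikeWeights(avg1), 1)
  expect_equal(PHat(avg1), 0.5)

  # two models, equal AIC
  avg2 <- suppressWarnings(modelAverage(list(mkFit(-100, 1), mkFit(-99, 2))))
  expect_equal(akaikeWeights(avg2), c(0.5, 0.5))

  # four models with dAIC = {0, 2, 4, 20}
  lls <- -100 - c(0, 2, 4, 20) / 2
  avg4 <- suppressWarnings(modelAverage(lapply(lls, mkFit, k = 1)))
  raw <- exp(-c(0, 2, 4, 20) / 2)
  expect_equal(akaikeWeights(avg4), raw / sum(raw), tolerance = 1e-12)

  # invariance to a constant shift of every log-likelihood
  avgS <- suppressWarnings(modelAverage(lapply(lls + 17.3, mkFit, k = 1)))
  expect_equal(akaikeWeights(avgS), akaikeWeights(avg4), tolerance = 1e-12)

  # differing truncation distances refuse to average
  other <- methods::new("DetectionFunctionFit", key = "half_normal",
                        sigma = 4, shape = NA_real_, cosCoef = numeric(0),
                        w = 12, PHat = 0.5, loglik = -100, aic = 202,
                        nParams = 1L, nObs = 100L,
                        vcov = matrix(NA_real_, 1, 1), binned = FALSE)
  expect_error(modelAverage(list(mkFit(-100, 1), other)), "truncation")
})

test_that("model-average P stays inside the member range", {
  w <- 10
  x <- sampleRadialDistances(1000, function(x) exp(-x^2 / 32), w, seed = 9)
  avg <- fitDetectionModelSet(x, w = w)
  P <- vapply(avg@fits, PHat, numeric(1))
  expect_gte(PHat(avg), min(P))
  expect_lte(PHat(avg), max(P))
  expect_equal(sum(akaikeWeights(avg)), 1, tolerance = 1e-12)
})

test_that("encounter-rate mean and variance follow the weighted estimator", {
  # equal counts, equal effort: zero variance
  er0 <- encounterRate(rep(4, 6), rep(100, 6))
  expect_equal(er0@epsilonBar, 4)
  expect_equal(cv(er0), 0)

  # K = 2, equal effort, counts {0, 2}: var = 1, cv = 100%
  er <- encounterRate(c(0, 2), c(50, 50))
  expect_equal(er@epsilonBar, 1)
  expect_equal(er@varEpsilon, 1)
  expect_equal(cv(er), 1)

  expect_error(encounterRate(c(0, 0), c(1, 1)), "zero")
  expect_error(encounterRate(3, 1), "two cameras")
})

test_that("encounter-rate variance is calibrated against Poisson truth", {
  K <- 60; lambda <- 3
  withr::with_seed(100, {
    vhat <- replicate(500, {
      n <- stats::rpois(K, lambda)
      if (all(n == 0)) return(NA_real_)
      encounterRate(n, rep(1000, K))@varEpsilon
    })
  })
  # true variance of the mean of K Poisson(lambda) counts
  expect_lt(abs(mean(vhat, na.rm = TRUE) - lambda / K) / (lambda / K), 0.15)
})

test_that("the worked density example evaluates to 200 per km^2", {
  avg <- suppressWarnings(modelAverage(list(makeDetFit(PHat = 0.5, w = 10))))
  act <- makeActivity(a = 0.5)
  den <- estimateDensity(counts = 875, efforts = 1e6, detection = avg,
                         activity = act, t = 2, theta = 0.7, w = 10)
  expect_equal(densityPerKm2(den), 200, tolerance = 1e-12)
})

test_that("density is linear in counts, inverse in effort and availability", {
  avg <- suppressWarnings(modelAverage(list(makeDetFit(PHat = 0.4, w = 10))))
  act <- makeActivity(a = 0.5)
  base <- estimateDensity(c(400, 475), c(5e5, 5e5), avg, act,
                          t = 2, theta = 0.7, w = 10)
  doubledT <- estimateDensity(c(400, 475), c(1e6, 1e6), avg, act,
                              t = 2, theta = 0.7, w = 10)
  doubledN <- estimateDensity(c(800, 950), c(5e5, 5e5), avg, act,
                              t = 2, theta = 0.7, w = 10)
  halvedA <- estimateDensity(c(400, 475), c(5e5, 5e5), avg, makeActivity(0.25),
                             t = 2, theta = 0.7, w = 10)
  expect_equal(densityPerKm2(doubledT), densityPerKm2(base) / 2)
  expect_equal(densityPerKm2(doubledN), densityPerKm2(base) * 2)
  expect_equal(densityPerKm2(halvedA), densityPerKm2(base) * 2)
})

test_that("density is equivariant under a change of distance units", {
  # metres -> centimetres: w and sigma scale by 100, P is unchanged, and the
  # per-area density scales by 1e-4, i.e. reported DHat scales by 1e-4.
  actM <- makeActivity(0.5)
  avgM <- suppressWarnings(modelAverage(list(makeDetFit(PHat = 0.37, w = 10,
                                                        sigma = 4))))
  avgCm <- suppressWarnings(modelAverage(list(makeDetFit(PHat = 0.37,
                                                         w = 1000,
                                                         sigma = 400))))
  dM <- estimateDensity(c(300, 200), c(4e5, 4e5), avgM, actM,
                        t = 2, theta = 0.73, w = 10)
  dCm <- estimateDensity(c(300, 200), c(4e5, 4e5), avgCm, actM,
                         t = 2, theta = 0.73, w = 1000)
  expect_equal(densityPerKm2(dCm) * 1e4, densityPerKm2(dM), tolerance = 1e-9)
  # P itself is scale-free
  expect_equal(camsnap:::averageDetection("half_normal", 400, NA_real_,
                                          numeric(0), 1000),
               camsnap:::averageDetection("half_normal", 4, NA_real_,
                                          numeric(0), 10),
               tolerance = 1e-9)
})

test_that("delta-method CV composition reproduces hand-worked values", {
  expect_equal(deltaCV(16, 4, 8), sqrt(336), tolerance = 1e-12)
  expect_equal(round(deltaCV(16, 4, 8)), 18)
  expect_equal(round(deltaCV(34, 9, 44)), 56)
  expect_equal(deltaCV(0, 0, 0), 0)
  expect_error(deltaCV(-1, 0, 0), "non-negative")
  # dominates each component; equality only when the others vanish
  expect_gte(deltaCV(10, 3, 4), 10)
  expect_equal(deltaCV(10, 0, 0), 10)
})

test_that("density CV is never below its largest component", {
  avg <- suppressWarnings(modelAverage(list(makeDetFit(PHat = 0.4, w = 10))))
  act <- makeActivity(a = 0.5, cvA = 0.08)
  den <- estimateDensity(c(10, 30, 20), c(1e5, 1e5, 1e5), avg, act,
                         t = 2, theta = 0.7, w = 10)
  expect_gte(cv(den), cv(den@encounter) - 1e-9)
  expect_gte(cv(den), 0.08 - 1e-9)
})

test_that("bootstrap CV behaves like sampling theory and is deterministic", {
  expect_equal(as.numeric(bootstrapCv(rep(5, 40), mean, B = 50, seed = 1)), 0)

  withr::with_seed(5, {
    x <- stats::rnorm(100, mean = 10, sd = 1)
  })
  cvB <- as.numeric(bootstrapCv(x, mean, B = 999, seed = 5))
  # CV of a mean of 100 N(10,1) draws is ~ 1/sqrt(100)/10 = 1%
  expect_lt(abs(cvB - 0.01), 0.003)

  again <- as.numeric(bootstrapCv(x, mean, B = 999, seed = 5))
  expect_identical(cvB, again)

  # failure fraction above 20% is an error
  flaky <- function(z) if (stats::runif(1) < 0.5) stop("no") else mean(z)
  expect_error(bootstrapCv(x, flaky, B = 99, seed = 2), "failed on")
})
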