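# Point-transect detection functions: half-normal and hazard-rate keys with
# cosine adjustments, maximum-likelihood fitting to exact or binned radial
# distances, and AIC model averaging.

#' @noRd
keyFunction <- function(x, key, sigma, shape) {
  switch(key,
    half_normal = exp(-x^2 / (2 * sigma^2)),
    hazard_rate = {
      g <- 1 - exp(-(x / sigma)^(-shape))
      g[x == 0] <- 1
      g
    },
    stop("unknown key: ", key, call. = FALSE))
}

#' @noRd
adjustmentSeries <- function(x, cosCoef, w) {
  if (!length(cosCoef)) return(rep(1, length(x)))
  s <- rep(1, length(x))
  for (j in seq_along(cosCoef))
    s <- s + cosCoef[j] * cos(j * pi * x / w)
  s
}

#' @noRd
rawDetection <- function(x, key, sigma, shape, cosCoef, w) {
  g <- keyFunction(x, key, sigma, shape) * adjustmentSeries(x, cosCoef, w)
  scale0 <- adjustmentSeries(0, cosCoef, w)   # key(0) = 1 by construction
  g / scale0
}

#' Evaluate a fitted detection function
#'
#' Probability that an animal at radial distance `x` from the camera is
#' detected at a snapshot moment. The key function (half-normal
#' `exp(-x^2 / 2 sigma^2)` or hazard-rate `1 - exp(-(x/sigma)^-b)`) is
#' multiplied by the cosine adjustment series `1 + sum_j a_j cos(j pi x / w)`,
#' rescaled so that g(0) = 1, and clipped to [0, 1].
#'
#' @param x distances in metres, all within `[0, w]`.
#' @param fit a [DetectionFunctionFit-class].
#' @return detection probabilities in [0, 1].
#' @export
detectionG <- function(x, fit) {
  if (any(x < 0 | x > fit@w))
    stop("x must lie within [0, w]", call. = FALSE)
  g <- rawDetection(x, fit@key, fit@sigma, fit@shape, fit@cosCoef, fit@w)
  pmin(1, pmax(0, g))
}

# Gauss-Legendre nodes for the fixed quadrature used in fitting; 101 points
# on (0, w) keeps the integration error far below the statistical error.
#' @noRd
glRule <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 101) {
    key <- as.character(n)
    if (is.null(cache[[key]])) cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
    cache[[key]]
  }
})

#' @noRd
integrateGx <- function(key, sigma, shape, cosCoef, w, lower = 0, upper = w) {
  # integral of clipped g(x) * x over [lower, upper], fixed Gauss-Legendre;
  # narrow (per-bin) ranges need far fewer nodes than the full range, where
  # the hazard-rate key's shoulder demands a fine rule
  rule <- glRule(if ((upper - lower) / w > 0.5) 401 else 101)
  x <- lower + (upper - lower) * rule$x
  g <- rawDetection(x, key, sigma, shape, cosCoef, w)
  g <- pmin(1, pmax(0, g))
  (upper - lower) * sum(rule$w * g * x)
}

#' @noRd
averageDetection <- function(key, sigma, shape, cosCoef, w) {
  2 / w^2 * integrateGx(key, sigma, shape, cosCoef, w)
}

#' @noRd
nDetfunParams <- function(key, nAdjustments) {
  as.integer((if (key == "hazard_rate") 2L else 1L) + nAdjustments)
}

#' @noRd
unpackDetfunPar <- function(par, key) {
  sigma <- exp(par[1])
  if (key == "hazard_rate") {
    shape <- 1 + exp(par[2])
    cosCoef <- par[-(1:2)]
  } else {
    shape <- NA_real_
    cosCoef <- par[-1]
  }
  list(sigma = sigma, shape = shape, cosCoef = cosCoef)
}

#' Fit a point-transect detection function by maximum likelihood
#'
#' For exact distances the radial density is
#' `f(x) = g(x) x / integral(g(u) u du)` on (0, w]; for binned distances the
#' corresponding multinomial likelihood over the bins is maximised. Distances
#' beyond the truncation distance `w` are discarded before fitting. Field
#' distances read off reference markers are coarse, so the default mode bins
#' exact input distances into 1-metre bins; set `binned = FALSE` for the
#' exact-distance likelihood.
#'
#' @param distances numeric vector of radial distances in metres (ignored
#'   when `counts` is given).
#' @param key `"half_normal"` or `"hazard_rate"`.
#' @param nAdjustments number of cosine adjustment terms (0, 1 or 2).
#' @param w truncation distance in metres; defaults to the 95th percentile
#'   of the observed distances.
#' @param binned logical; bin exact distances before fitting (default TRUE).
#' @param binWidth bin width in metres for the default binning.
#' @param counts,breaks alternatively, pre-binned counts with their ordered,
#'   contiguous bin edges (length `length(counts) + 1`).
#' @return a [DetectionFunctionFit-class].
#' @examples
#' x <- abs(rnorm(500, 0, 4)) # half-normal-ish radial spread
#' fitDetectionFunction(x, key = "half_normal", w = 10)
#' @export
fitDetectionFunction <- function(distances = NULL,
                                 key = c("half_normal", "hazard_rate"),
                                 nAdjustments = 0, w = NULL, binned = TRUE,
                                 binWidth = 1, counts = NULL, breaks = NULL) {
  key <- match.arg(key)
  if (!nAdjustments %in% 0:2)
    stop("nAdjustments must be 0, 1 or 2", call. = FALSE)

  if (is.null(counts)) {
    if (is.null(w)) w <- as.numeric(stats::quantile(distances, 0.95))
    x <- distances[distances <= w & distances >= 0]
    n <- length(x)
    if (n < 10)
      stop("fewer than 10 observations within the truncation distance; ",
           "fit refused", call. = FALSE)
    if (binned) {
      breaks <- seq(0, w, by = binWidth)
      if (breaks[length(breaks)] < w) breaks <- c(breaks, w)
      counts <- as.numeric(table(cut(x, breaks, include.lowest = TRUE)))
    }
  } else {
    if (is.null(breaks) || length(breaks) != length(counts) + 1)
      stop("breaks must have length(counts) + 1", call. = FALSE)
    if (any(diff(breaks) <= 0))
      stop("breaks must be increasing (ordered, contiguous bins)",
           call. = FALSE)
    if (is.null(w)) w <- breaks[length(breaks)]
    n <- sum(counts)
    if (n < 10)
      stop("fewer than 10 observations within the truncation distance; ",
           "fit refused", call. = FALSE)
    binned <- TRUE
    x <- NULL
  }

  useBins <- binned
  nllExact <- function(par) {
    th <- unpackDetfunPar(par, key)
    series0 <- adjustmentSeries(0, th$cosCoef, w)
    if (series0 <= 1e-6) return(1e10)
    g <- rawDetection(x, key, th$sigma, th$shape, th$cosCoef, w)
    if (any(g <= 0)) return(1e10)
    g <- pmin(1, g)
    mu <- integrateGx(key, th$sigma, th$shape, th$cosCoef, w)
    if (!is.finite(mu) || mu <= 0) return(1e10)
    -(sum(log(g) + log(x)) - n * log(mu))
  }
  nllBinned <- function(par) {
    th <- unpackDetfunPar(par, key)
    series0 <- adjustmentSeries(0, th$cosCoef, w)
    if (series0 <= 1e-6) return(1e10)
    ints <- vapply(seq_len(length(breaks) - 1), function(j)
      integrateGx(key, th$sigma, th$shape, th$cosCoef, w,
                  breaks[j], breaks[j + 1]), numeric(1))
    if (any(!is.finite(ints)) || any(ints < 0) || sum(ints) <= 0) return(1e10)
    pj <- ints / sum(ints)
    if (any(pj[counts > 0] <= 0)) return(1e10)
    -sum(counts[counts > 0] * log(pj[counts > 0]))
  }
  nll <- if (useBins) nllBinned else nllExact

  # starting values: scale from the data spread, shape 2, no adjustment
  meanX <- if (!is.null(x)) mean(x) else {
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    sum(mids * counts) / n
  }
  sigma0 <- max(meanX / 1.5, w / 20)
  baseStart <- c(log(sigma0), if (key == "hazard_rate") log(1),
                 rep(0, nAdjustments))
  starts <- list(baseStart,
                 replace(baseStart, 1, log(min(sigma0 * 3, w))),
                 replace(baseStart, 1, log(sigma0 / 3)))

  best <- NULL
  for (s in starts) {
    f <- tryCatch(
      stats::optim(s, nll,
                   method = if (length(s) == 1) "BFGS" else "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(f) || !is.finite(f$value) || f$value >= 1e9) next
    if (is.null(best) || f$value < best$value - 1e-9) best <- f
  }
  if (is.null(best))
    stop("detection-function optimisation failed (", key, ", ",
         nAdjustments, " adjustments)", call. = FALSE)

  th <- unpackDetfunPar(best$par, key)

  # diagnostics: adjusted series range before rescaling, monotonicity after
  gridX <- seq(0, w, length.out = 201)
  series <- keyFunction(gridX, key, th$sigma, th$shape) *
    adjustmentSeries(gridX, th$cosCoef, w)
  if (any(series < -1e-9) || any(series > 1.2 + 1e-9))
    warning("adjusted detection series leaves [0, 1.2] before rescaling",
            call. = FALSE)
  gGrid <- pmin(1, pmax(0, series / adjustmentSeries(0, th$cosCoef, w)))
  if (any(diff(gGrid) > 1e-3))
    warning("adjusted detection function is non-monotonic", call. = FALSE)

  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  k <- nDetfunParams(key, nAdjustments)
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) <= 0))
    V <- matrix(NA_real_, k, k)

  PHat <- averageDetection(key, th$sigma, th$shape, th$cosCoef, w)
  ll <- -best$value
  methods::new("DetectionFunctionFit",
    key = key, sigma = th$sigma, shape = th$shape,
    cosCoef = as.numeric(th$cosCoef), w = w,
    PHat = min(1, PHat), loglik = ll, aic = 2 * k - 2 * ll,
    nParams = k, nObs = as.integer(n), vcov = V, binned = useBins)
}

#' @noRd
detfunPackPar <- function(fit) {
  c(log(fit@sigma),
    if (fit@key == "hazard_rate") log(fit@shape - 1),
    fit@cosCoef)
}

#' Sampling CV of a fit's average detection probability (delta method)
#'
#' Numerical gradient of P-hat with respect to the internal parameters,
#' propagated through the fit's covariance matrix.
#'
#' @param fit a [DetectionFunctionFit-class].
#' @return CV as a proportion, or `NA` when the covariance is unavailable.
#' @export
detectionPCv <- function(fit) {
  V <- fit@vcov
  if (any(is.na(V))) return(NA_real_)
  par <- detfunPackPar(fit)
  Pof <- function(p) {
    th <- unpackDetfunPar(p, fit@key)
    averageDetection(fit@key, th$sigma, th$shape, th$cosCoef, fit@w)
  }
  h <- pmax(1e-5, abs(par) * 1e-5)
  grad <- vapply(seq_along(par), function(i) {
    up <- par; up[i] <- up[i] + h[i]
    dn <- par; dn[i] <- dn[i] - h[i]
    (Pof(up) - Pof(dn)) / (2 * h[i])
  }, numeric(1))
  varP <- drop(t(grad) %*% V %*% grad)
  if (!is.finite(varP) || varP < 0) return(NA_real_)
  sqrt(varP) / fit@PHat
}

#' AIC-weighted model average of detection-function fits
#'
#' Akaike weights `w_i = exp(-dAIC_i / 2)` (renormalised) give the averaged
#' detection probability `P = sum w_i P_i`. Its CV combines each member's
#' sampling CV with the between-model spread:
#' `cvP^2 = sum w_i (cv_i^2 + (P_i - P)^2 / P^2)`.
#'
#' @param fits list of [DetectionFunctionFit-class] objects fitted to the
#'   same data and truncation distance.
#' @param memberCv optional numeric vector of member sampling CVs
#'   (proportions), e.g. from [bootstrapCv()]; defaults to the delta-method
#'   CVs from each fit's covariance ([detectionPCv()]).
#' @return a [ModelAverage-class].
#' @export
modelAverage <- function(fits, memberCv = NULL) {
  if (!length(fits)) stop("no fits to average", call. = FALSE)
  ws <- vapply(fits, function(f) f@w, numeric(1))
  if (max(ws) - min(ws) > 1e-9)
    stop("fits use differing truncation distances", call. = FALSE)
  aic <- vapply(fits, function(f) f@aic, numeric(1))
  delta <- aic - min(aic)
  weights <- exp(-delta / 2)
  weights <- weights / sum(weights)
  P <- vapply(fits, function(f) f@PHat, numeric(1))
  PBar <- sum(weights * P)

  if (is.null(memberCv))
    memberCv <- vapply(fits, detectionPCv, numeric(1))
  if (any(is.na(memberCv))) {
    warning("member sampling CV unavailable for some fit(s); treated as 0",
            call. = FALSE)
    memberCv[is.na(memberCv)] <- 0
  }
  cvP <- sqrt(sum(weights * (memberCv^2 + (P - PBar)^2 / PBar^2)))
  methods::new("ModelAverage", fits = fits, weights = weights,
               PBar = PBar, cvP = cvP)
}

#' Fit the standard CTDS candidate set and average it
#'
#' Fits half-normal and hazard-rate keys with 0, 1 and 2 cosine adjustment
#' terms (six candidates), drops candidates whose optimisation fails, and
#' returns the AIC-weighted average.
#'
#' @inheritParams fitDetectionFunction
#' @param quiet suppress per-candidate warnings (default TRUE).
#' @return a [ModelAverage-class].
#' @export
fitDetectionModelSet <- function(distances, w = NULL, binned = TRUE,
                                 binWidth = 1, quiet = TRUE) {
  if (is.null(w)) w <- as.numeric(stats::quantile(distances, 0.95))
  fits <- list()
  for (key in c("half_normal", "hazard_rate")) {
    for (adj in 0:2) {
      f <- tryCatch({
        if (quiet)
          suppressWarnings(fitDetectionFunction(distances, key = key,
                                                nAdjustments = adj, w = w,
                                                binned = binned,
                                                binWidth = binWidth))
        else
          fitDetectionFunction(distances, key = key, nAdjustments = adj,
                               w = w, binned = binned, binWidth = binWidth)
      }, error = function(e) NULL)
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
  }
  if (!length(fits)) stop("no detection-function candidate converged",
                          call. = FALSE)
  if (quiet) suppressWarnings(modelAverage(fits)) else modelAverage(fits)
}
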