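# Single-season occupancy: direct maximum likelihood on the zero-inflated
# binomial likelihood
#
#   L(psi, p) = [ psi^n. prod_t p_t^{n_t} (1 - p_t)^{n. - n_t} ]
#               * [ psi prod_t (1 - p_t) + (1 - psi) ]^{N - n.}
#
# evaluated site-wise so that occasions with missing effort contribute no
# detection factor; the balanced form above is recovered exactly when no cell
# is missing.

#' Occupancy log-likelihood
#'
#' Log-likelihood of a single-season occupancy model with occupancy
#' probability `psi` and per-occasion detection probability `p` (a scalar for
#' the constant-p model, or a vector of length T). Computed as a product of
#' per-site likelihoods: a site with at least one detection must be occupied;
#' a site with none is either occupied-and-missed or unoccupied. Missing
#' cells (no camera effort) contribute nothing.
#'
#' @param psi occupancy probability in (0, 1).
#' @param p detection probability in (0, 1); scalar or length `nOccasions`.
#' @param history a [DetectionHistory-class].
#' @return the log-likelihood (a single non-positive number for any
#'   realisable history).
#' @export
occupancyLoglik <- function(psi, p, history) {
  m <- history@matrix
  Tocc <- ncol(m)
  if (length(p) == 1L) p <- rep(p, Tocc)
  if (length(p) != Tocc)
    stop("p must be scalar or have one entry per occasion", call. = FALSE)
  if (psi <= 0 || psi >= 1 || any(p <= 0 | p >= 1))
    stop("psi and p must lie strictly in (0, 1)", call. = FALSE)
  if (any(apply(m, 1, function(r) all(is.na(r)))))
    stop("history has all-missing site row(s)", call. = FALSE)

  logP <- matrix(log(p), nrow(m), Tocc, byrow = TRUE)
  log1mP <- matrix(log1p(-p), nrow(m), Tocc, byrow = TRUE)
  obs <- !is.na(m)
  cell <- ifelse(obs, ifelse(m == 1L, logP, log1mP), 0)
  siteDetLog <- rowSums(cell)                   # log prod p^d (1-p)^(1-d)
  siteMissLog <- rowSums(ifelse(obs, log1mP, 0))  # log prod (1-p) over observed
  detected <- apply(m, 1, function(r) any(r == 1L, na.rm = TRUE))
  llDet <- sum(log(psi) + siteDetLog[detected])
  llUndet <- sum(log(psi * exp(siteMissLog[!detected]) + (1 - psi)))
  llDet + llUndet
}

#' @noRd
historySufficientStats <- function(history) {
  m <- history@matrix
  obs <- !is.na(m)
  k <- rowSums(obs)                       # occasions observed per site
  d <- rowSums(m == 1L, na.rm = TRUE)     # detections per site
  detected <- d > 0
  list(
    nDet = sum(detected),
    D = sum(d[detected]),                 # total detections
    M = sum(k[detected] - d[detected]),   # non-detections at detected sites
    kUndet = table(k[!detected])          # observed-occasion counts, undetected sites
  )
}

#' @noRd
loglikGridConstantP <- function(stats, psiGrid, pGrid) {
  # matrix [psi x p] of log-likelihood values under constant p
  G1 <- length(psiGrid); G2 <- length(pGrid)
  detPart <- stats$nDet * log(psiGrid)
  pPart <- stats$D * log(pGrid) + stats$M * log1p(-pGrid)
  ll <- outer(detPart, pPart, `+`)
  if (length(stats$kUndet)) {
    ks <- as.numeric(names(stats$kUndet))
    cs <- as.numeric(stats$kUndet)
    for (j in seq_along(ks)) {
      q <- (1 - pGrid)^ks[j]                       # length G2
      ll <- ll + cs[j] * log(outer(psiGrid, q) + (1 - psiGrid))
    }
  }
  ll
}

#' Fit a single-season occupancy model
#'
#' Maximises [occupancyLoglik()] over logit-transformed parameters with a
#' quasi-Newton optimizer and multiple starting points (naive-based, central
#' and spread starts; the best optimum is kept). Standard errors come from
#' the inverse observed information on the logit scale, back-transformed by
#' the delta method. Estimates within numerical reach of the boundary are
#' flagged (`boundary = TRUE`) and their standard errors set to `NA`.
#'
#' @param history a [DetectionHistory-class].
#' @param pStructure `"constant"` for a single detection probability, or
#'   `"time"` for one per occasion.
#' @return an [OccupancyFit-class].
#' @examples
#' sim <- simulateOccupancy(N = 100, T = 7, psi = 0.6, p = 0.3, seed = 1)
#' fitOccupancy(sim$history)
#' @export
fitOccupancy <- function(history, pStructure = c("constant", "time")) {
  pStructure <- match.arg(pStructure)
  m <- history@matrix
  N <- nrow(m); Tocc <- ncol(m)
  if (all(is.na(m))) stop("all-missing history", call. = FALSE)
  naive <- naiveOccupancy(history)
  nP <- if (pStructure == "constant") 1L else Tocc

  ndot <- nDot(history)
  allOnes <- all(m[!is.na(m)] == 1L)
  if (ndot == 0L || allOnes) {
    warning("boundary history (", if (ndot == 0L) "no" else "all",
            " detections): estimates at the boundary, SEs unreliable",
            call. = FALSE)
    eps <- 1e-6
    psiB <- if (ndot == 0L) eps else 1 - eps
    pB <- rep(if (ndot == 0L) eps else 1 - eps, nP)
    return(methods::new("OccupancyFit",
      psiHat = round(psiB), pHat = round(pB),
      sePsi = NA_real_, seP = rep(NA_real_, nP),
      loglik = occupancyLoglik(psiB, pB, history),
      converged = TRUE, boundary = TRUE,
      nSites = N, nOccasions = Tocc, naiveOccupancy = naive,
      pStructure = pStructure))
  }

  squash <- function(x) pmin(1 - 1e-12, pmax(1e-12, stats::plogis(x)))
  nll <- function(par) {
    if (any(!is.finite(par))) return(1e10)
    -occupancyLoglik(squash(par[1]), squash(par[-1]), history)
  }

  clamp <- function(x, lo = 0.02, hi = 0.98) pmin(hi, pmax(lo, x))
  obsPerOccasion <- colSums(!is.na(m))
  pNaive <- clamp(sum(m == 1L, na.rm = TRUE) /
                    max(1, sum(!is.na(m[rowSums(m == 1L, na.rm = TRUE) > 0, ,
                                        drop = FALSE]))))
  starts <- list(
    c(clamp(naive), rep(pNaive, nP)),
    c(0.5, rep(0.5, nP)),
    c(0.2, rep(0.2, nP)),
    c(0.8, rep(0.2, nP)),
    c(0.2, rep(0.8, nP)))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(stats::qlogis(s), nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12,
                                  ndeps = rep(1e-6, 1L + nP))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best)) stop("occupancy optimisation failed from every start",
                          call. = FALSE)

  # Newton polish on the logit scale until the gradient norm drops below
  # 1e-8: quasi-Newton alone can stall in flat directions of psi.
  par <- best$par
  value <- best$value
  numGrad <- function(f, x, h = 1e-6) {
    vapply(seq_along(x), function(i) {
      up <- x; up[i] <- up[i] + h
      dn <- x; dn[i] <- dn[i] - h
      (f(up) - f(dn)) / (2 * h)
    }, numeric(1))
  }
  for (iter in 1:25) {
    g <- numGrad(nll, par)
    if (max(abs(g)) < 1e-8) break
    H <- tryCatch(stats::optimHess(par, nll), error = function(e) NULL)
    step <- if (!is.null(H))
      tryCatch(solve(H, g), error = function(e) g) else g
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      vc <- nll(cand)
      if (is.finite(vc) && vc <= value + 1e-12) { par <- cand; value <- vc; break }
      lambda <- lambda / 2
      if (lambda < 1e-6) break
    }
    if (lambda < 1e-6) break
  }
  best$par <- par
  best$value <- value
  psi <- stats::plogis(par[1])
  p <- stats::plogis(par[-1])
  boundary <- any(abs(par) > 8)

  sePsi <- NA_real_; seP <- rep(NA_real_, nP)
  if (!boundary) {
    H <- tryCatch(stats::optimHess(par, nll), error = function(e) NULL)
    V <- if (!is.null(H))
      tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(V) && all(diag(V) > 0)) {
      seLogit <- sqrt(diag(V))
      sePsi <- seLogit[1] * psi * (1 - psi)
      seP <- seLogit[-1] * p * (1 - p)
    }
  }

  methods::new("OccupancyFit",
    psiHat = psi, pHat = p, sePsi = sePsi, seP = seP,
    loglik = -best$value,
    converged = best$convergence == 0L, boundary = boundary,
    nSites = N, nOccasions = Tocc, naiveOccupancy = naive,
    pStructure = pStructure)
}

#' Grid-search maximiser of the occupancy likelihood
#'
#' Brute-force argmax of the constant-p occupancy likelihood over a uniform
#' `gridSize` x `gridSize` grid on (0,1)^2, optionally followed by
#' `refine` re-gridding passes of the same size spanning one original grid
#' step around the incumbent maximum. Serves as an independent oracle for
#' [fitOccupancy()]: with two refinement passes the argmax is located far
#' below the optimizer's tolerance.
#'
#' @param history a [DetectionHistory-class].
#' @param gridSize points per axis (>= 100).
#' @param refine number of refinement passes (default 0: single pass).
#' @return named numeric `c(psi=, p=)`.
#' @export
oracleGridFit <- function(history, gridSize = 1000, refine = 0) {
  if (gridSize < 100) stop("gridSize must be >= 100", call. = FALSE)
  stats <- historySufficientStats(history)
  lo <- c(0, 0); hi <- c(1, 1)
  res <- NULL
  for (pass in seq_len(refine + 1)) {
    psiGrid <- lo[1] + (seq_len(gridSize) - 0.5) / gridSize * (hi[1] - lo[1])
    pGrid <- lo[2] + (seq_len(gridSize) - 0.5) / gridSize * (hi[2] - lo[2])
    ll <- loglikGridConstantP(stats, psiGrid, pGrid)
    idx <- arrayInd(which.max(ll), dim(ll))
    res <- c(psi = psiGrid[idx[1]], p = pGrid[idx[2]])
    # re-grid over +/- 3 steps: a discrete argmax can sit a few cells off
    # the continuous maximiser along the psi-p ridge
    step <- c((hi[1] - lo[1]), (hi[2] - lo[2])) / gridSize
    lo <- pmax(c(1e-12, 1e-12), res - 3 * step)
    hi <- pmin(c(1 - 1e-12, 1 - 1e-12), res + 3 * step)
  }
  res
}

#' Tidy a set of occupancy fits
#'
#' @param fits named list of [OccupancyFit-class] objects (names become the
#'   `label` column, e.g. "species:year").
#' @return data.frame with one row per fit, mirroring the per-species-year
#'   reporting layout: label, psi, sePsi, p, seP, naive, nDetectedSites,
#'   converged, reliable.
#' @export
tidyOccupancyFits <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(label = nm, psi = f@psiHat, sePsi = f@sePsi,
               p = mean(f@pHat), seP = mean(f@seP),
               naive = f@naiveOccupancy,
               nDetectedSites = as.integer(round(f@naiveOccupancy * f@nSites)),
               converged = f@converged,
               reliable = !f@boundary &&
                 round(f@naiveOccupancy * f@nSites) >= 3,
               stringsAsFactors = FALSE)
  }))
}
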