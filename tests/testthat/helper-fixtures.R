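# Shared fixtures and independent oracles, all built in code.

utcTime <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# A small internal-model fixture: 3 deployments, 5 occurrences
# (3 animal, 1 blank, 1 unknown).
makeCamtrapFixture <- function() {
  dep <- data.frame(
    deploymentID = c("d1", "d2", "d3"),
    locationID = c("L1", "L2", "L3"),
    latitude = c(42.001, 42.005, 42.009),
    longitude = c(-8.201, -8.205, -8.209),
    start = utcTime(c("2019-05-07T08:00:00Z", "2019-05-07T09:00:00Z",
                      "2019-05-08T08:00:00Z")),
    end = utcTime(c("2019-10-08T08:00:00Z", "2019-10-08T09:00:00Z",
                    "2019-10-09T08:00:00Z")),
    sensitivity = c("high", "high", "medium"),
    cameraAngle = c(0.73, 0.73, 0.73),
    stringsAsFactors = FALSE)
  occ <- data.frame(
    occurrenceID = paste0("s", 1:5),
    deploymentID = c("d1", "d1", "d2", "d3", "d3"),
    timestamp = utcTime(c("2019-05-10T21:15:00Z", "2019-06-01T04:30:00Z",
                          "2019-05-12T23:00:00Z", "2019-05-20T02:10:00Z",
                          "2019-07-04T22:45:00Z")),
    taxon = c("Capreolus capreolus", "Sus scrofa", "Capreolus capreolus",
              "blank", "unknown"),
    observationType = c("animal", "animal", "animal", "blank", "unknown"),
    nImages = c(12L, 3L, 7L, 1L, 2L),
    distances = c("2.50;4.00", "6.00", "", "", ""),
    isFirstTrigger = rep(TRUE, 5),
    stringsAsFactors = FALSE)
  list(deployments = dep, occurrences = occ)
}

# Brute-force single-linkage-in-time grouping oracle: O(n^2) chaining.
bruteGroupSizes <- function(media, gapSeconds) {
  sizes <- integer(0)
  for (dep in unique(media$deploymentID)) {
    ts <- sort(as.numeric(media$timestamp[media$deploymentID == dep]))
    cur <- 1L
    for (i in seq_along(ts)[-1]) {
      if (ts[i] - ts[i - 1] <= gapSeconds) cur <- cur + 1L
      else { sizes <- c(sizes, cur); cur <- 1L }
    }
    sizes <- c(sizes, cur)
  }
  sizes
}

# Brute-force occupancy likelihood: per site, enumerate the latent
# occupied/unoccupied state explicitly.
bruteOccupancyLik <- function(psi, p, m) {
  Tocc <- ncol(m)
  if (length(p) == 1) p <- rep(p, Tocc)
  lik <- 1
  for (i in seq_len(nrow(m))) {
    lOcc <- psi
    for (t in seq_len(Tocc)) {
      d <- m[i, t]
      if (is.na(d)) next
      lOcc <- lOcc * if (d == 1) p[t] else (1 - p[t])
    }
    lUnocc <- if (any(m[i, ] == 1, na.rm = TRUE)) 0 else (1 - psi)
    lik <- lik * (lOcc + lUnocc)
  }
  lik
}

# Balanced-history likelihood straight from the printed closed form,
# via the sufficient statistics n., n_t.
closedFormOccupancyLik <- function(psi, p, m) {
  N <- nrow(m); Tocc <- ncol(m)
  if (length(p) == 1) p <- rep(p, Tocc)
  ndot <- sum(apply(m, 1, function(r) any(r == 1)))
  nt <- colSums(m == 1)
  psi^ndot * prod(p^nt * (1 - p)^(ndot - nt)) *
    (psi * prod(1 - p) + (1 - psi))^(N - ndot)
}

# Radial point-transect distances under a detection function: candidates
# from the uniform-in-area density 2x/w^2, thinned by g.
sampleRadialDistances <- function(n, g, w, seed = NULL) {
  draw <- function(k) {
    x <- w * sqrt(stats::runif(k))
    x[stats::runif(k) < g(x)]
  }
  run <- function() {
    out <- numeric(0)
    while (length(out) < n) out <- c(out, draw(2L * n))
    out[seq_len(n)]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Construct a consistent DetectionFunctionFit without fitting (for worked
# examples that fix P directly).
makeDetFit <- function(PHat = 0.5, w = 10, sigma = 5, loglik = -10) {
  methods::new("DetectionFunctionFit", key = "half_normal", sigma = sigma,
               shape = NA_real_, cosCoef = numeric(0), w = w, PHat = PHat,
               loglik = loglik, aic = 2 * 1 - 2 * loglik, nParams = 1L,
               nObs = 100L, vcov = matrix(NA_real_, 1, 1), binned = FALSE)
}

makeActivity <- function(a = 0.5, cvA = 0) {
  methods::new("ActivityEstimate", a = a, cvA = cvA, kappa = 1,
               nTimes = 100L)
}
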