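# Synthetic camera-trap scenarios with known truth: occupancy histories,
# CTDS snapshot data, and Camtrap DP emission.

#' Default synthetic scenario truth
#'
#' Mirrors the study design the package targets: a grid of 64 cameras about
#' 500 m apart, deployed for one 150-day summer season, with a 42-degree
#' (0.73 rad) field of view, 10 m truncation distance and a 2 s snapshot
#' interval. Truth defaults: density 5 individuals/km^2, half-normal
#' detection with sigma = 4 m, activity level 0.5 (active 06:00-18:00),
#' occupancy 0.6 with daily detection probability 0.3.
#'
#' @param nCameras,deployDays camera grid size and deployment length (days).
#' @param theta,w,t CTDS constants (radians, metres, seconds).
#' @param DTrue true density per km^2.
#' @param detfunKey,detfunSigma,detfunShape true detection function.
#' @param activityWindows 2-column matrix of active hour intervals; the
#'   activity level is their total width / 24.
#' @param psiTrue,pTrue occupancy truth.
#' @param seed integer seed recorded in the truth object.
#' @return a [ScenarioTruth-class].
#' @export
defaultScenario <- function(nCameras = 64, deployDays = 150, theta = 0.73,
                            w = 10, t = 2, DTrue = 5,
                            detfunKey = "half_normal", detfunSigma = 4,
                            detfunShape = NA_real_,
                            activityWindows = matrix(c(6, 18), 1),
                            psiTrue = 0.6, pTrue = 0.3, seed = 1L) {
  aTrue <- sum(activityWindows[, 2] - activityWindows[, 1]) / 24
  methods::new("ScenarioTruth", psiTrue = psiTrue, pTrue = pTrue,
               DTrue = DTrue, detfunKey = detfunKey,
               detfunSigma = detfunSigma, detfunShape = detfunShape,
               aTrue = aTrue, activityWindows = activityWindows,
               nCameras = as.integer(nCameras), deployDays = deployDays,
               theta = theta, w = w, t = t, seed = as.integer(seed))
}

#' Simulate a single-season occupancy detection history
#'
#' Sites are occupied i.i.d. Bernoulli(psi); at occupied sites, detection on
#' each occasion is Bernoulli(p); cells are masked missing at rate
#' `missingFraction`. The latent occupancy states are retained for
#' bookkeeping checks.
#'
#' @param N,T number of sites and occasions.
#' @param psi,p occupancy and detection probability.
#' @param missingFraction fraction of cells masked `NA` (default 0).
#' @param seed integer seed.
#' @return list with `history` (a [DetectionHistory-class]), `z` (latent
#'   occupancy vector) and `truth` (a [ScenarioTruth-class]).
#' @export
simulateOccupancy <- function(N, T, psi, p, missingFraction = 0, seed = 1L) {
  withSeed(seed, {
    z <- stats::rbinom(N, 1, psi)
    y <- matrix(stats::rbinom(N * T, 1, p), N, T) * z
    if (missingFraction > 0) {
      mask <- matrix(stats::runif(N * T) < missingFraction, N, T)
      # keep at least one observed occasion per site
      for (i in which(rowSums(!mask) == 0)) mask[i, sample.int(T, 1)] <- FALSE
      y[mask] <- NA_integer_
    }
    truth <- defaultScenario(psiTrue = psi, pTrue = p, seed = seed)
    list(history = detectionHistoryFromMatrix(y), z = z, truth = truth)
  })
}

#' @noRd
sampleActivityTimes <- function(n, windows) {
  if (n == 0) return(numeric(0))
  width <- windows[, 2] - windows[, 1]
  wi <- sample.int(nrow(windows), n, replace = TRUE, prob = width)
  hours <- windows[wi, 1] + stats::runif(n) * width[wi]
  hours / 24 * 2 * pi
}

#' Simulate CTDS snapshot data from a scenario
#'
#' At each snapshot moment, independently for each camera, an animal is
#' present in the camera's sector with probability `D theta w^2 / 2` (the
#' expected number of animals in the sector, valid for the low densities
#' camera traps sample), is available with probability `aTrue`, sits at a
#' radial distance drawn from the uniform-in-area density `2x / w^2`, and is
#' detected with probability `g(x)` under the true detection function.
#' Presence is i.i.d. across snapshots (no movement autocorrelation), which
#' keeps the moment-based estimators exactly unbiased; `clustered = TRUE`
#' multiplies presences into geometric-size bursts to stress variance
#' estimators only.
#'
#' @param scenario a [ScenarioTruth-class].
#' @param nReplicates number of independent survey replicates.
#' @param seed integer seed (defaults to the scenario's).
#' @param clustered simulate burst arrivals (default FALSE).
#' @param meanClusterSize mean burst size when `clustered`.
#' @return list of replicates; each has `counts` (per-camera n_k),
#'   `efforts` (per-camera T_k, seconds), `distances` (detected radial
#'   distances, metres), `camera` (camera index per detection), `times`
#'   (detection times of day, radians) and `truth`.
#' @export
simulateCtds <- function(scenario, nReplicates = 1, seed = NULL,
                         clustered = FALSE, meanClusterSize = 5) {
  if (is.null(seed)) seed <- scenario@seed
  K <- scenario@nCameras
  effort <- rep(scenario@deployDays * 86400, K)
  nSnap <- floor(effort[1] / scenario@t)
  pPresent <- scenario@DTrue * 1e-6 * scenario@theta * scenario@w^2 / 2
  if (pPresent > 1) stop("density too high for the Bernoulli snapshot model",
                         call. = FALSE)
  gTrue <- function(x) {
    g <- rawDetection(x, scenario@detfunKey, scenario@detfunSigma,
                      scenario@detfunShape, numeric(0), scenario@w)
    pmin(1, pmax(0, g))
  }
  PTrue <- averageDetection(scenario@detfunKey, scenario@detfunSigma,
                            scenario@detfunShape, numeric(0), scenario@w)
  expDet <- K * nSnap * pPresent * scenario@aTrue * PTrue
  if (expDet < 50)
    warning(sprintf(paste0("expected detections per replicate is %.1f ",
                           "(< 50): recovery tests will be underpowered"),
                    expDet), call. = FALSE)

  withSeed(seed, {
    lapply(seq_len(nReplicates), function(r) {
      nPresent <- stats::rbinom(K, nSnap, pPresent)
      if (clustered) {
        # burst arrivals: same mean, inflated between-camera variance
        nPresent <- vapply(nPresent, function(np) {
          nBurst <- stats::rpois(1, np / meanClusterSize)
          sum(1 + stats::rgeom(nBurst, 1 / meanClusterSize))
        }, numeric(1))
      }
      nAvail <- stats::rbinom(K, nPresent, scenario@aTrue)
      total <- sum(nAvail)
      cam <- rep.int(seq_len(K), nAvail)
      x <- scenario@w * sqrt(stats::runif(total))
      det <- stats::runif(total) < gTrue(x)
      camDet <- cam[det]
      list(counts = tabulate(camDet, nbins = K), efforts = effort,
           distances = x[det], camera = camDet,
           times = sampleActivityTimes(sum(det), scenario@activityWindows),
           truth = scenario)
    })
  })
}

#' Emit a simulated scenario as Camtrap DP files
#'
#' Builds a deployment table for the scenario's camera grid (8 x 8 cells,
#' 500 m spacing) and an observation table holding one sequence per detected
#' occurrence event, plus blank sequences at rate `blankFraction`, then
#' writes both via [writeCamtrapDP()].
#'
#' @param dataset one replicate from [simulateCtds()].
#' @param outDir output directory.
#' @param species scientific name to assign to the simulated animal.
#' @param blankFraction fraction of all emitted sequences that are blank.
#' @param startDate first deployment day.
#' @param seed integer seed for blank placement and timestamps.
#' @return invisibly, the written file paths; the internal model is attached
#'   as attribute `"model"`.
#' @export
emitCamtrapDP <- function(dataset, outDir, species = "Capreolus capreolus",
                          blankFraction = 0, startDate = as.Date("2019-05-07"),
                          seed = 1L) {
  truth <- dataset$truth
  K <- truth@nCameras
  side <- ceiling(sqrt(K))
  row <- (seq_len(K) - 1) %/% side
  col <- (seq_len(K) - 1) %% side
  lat0 <- 42.0; lon0 <- -8.2
  start <- as.POSIXct(paste0(startDate, "T08:00:00Z"),
                      format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  dep <- data.frame(
    deploymentID = sprintf("dep_%03d", seq_len(K)),
    locationID = sprintf("loc_%03d", seq_len(K)),
    latitude = round(lat0 + row * 500 / 111320, 3),
    longitude = round(lon0 + col * 500 / (111320 * cos(lat0 * pi / 180)), 3),
    start = start,
    end = start + truth@deployDays * 86400,
    sensitivity = "high",
    cameraAngle = truth@theta,
    stringsAsFactors = FALSE)

  withSeed(seed, {
    nObs <- length(dataset$camera)
    day <- sample.int(max(1, floor(truth@deployDays)), nObs, replace = TRUE) - 1
    frac <- (dataset$times / (2 * pi)) * 86400
    ts <- start + day * 86400 + frac
    occ <- data.frame(
      occurrenceID = sprintf("seq_%05d", seq_len(nObs)),
      deploymentID = dep$deploymentID[dataset$camera],
      timestamp = ts,
      taxon = species,
      observationType = "animal",
      nImages = 1L + stats::rpois(nObs, 3),
      distances = sprintf("%.2f", dataset$distances),
      isFirstTrigger = TRUE,
      stringsAsFactors = FALSE)

    if (blankFraction > 0) {
      nBlank <- round(blankFraction / (1 - blankFraction) * nObs)
      if (nBlank > 0) {
        camB <- sample.int(K, nBlank, replace = TRUE)
        tsB <- start + (stats::runif(nBlank) * truth@deployDays) * 86400
        blank <- data.frame(
          occurrenceID = sprintf("seqb_%05d", seq_len(nBlank)),
          deploymentID = dep$deploymentID[camB],
          timestamp = tsB,
          taxon = "blank",
          observationType = "blank",
          nImages = 1L + stats::rpois(nBlank, 3),
          distances = "",
          isFirstTrigger = TRUE,
          stringsAsFactors = FALSE)
        occ <- rbind(occ, blank)
      }
    }
    occ <- occ[order(occ$deploymentID, occ$timestamp), , drop = FALSE]
    rownames(occ) <- NULL
    occ$timestamp <- as.POSIXct(floor(as.numeric(occ$timestamp)),
                                origin = "1970-01-01", tz = "UTC")
    files <- writeCamtrapDP(dep, occ, outDir)
    attr(files, "model") <- list(deployments = dep, occurrences = occ)
    invisible(files)
  })
}

#' Serialise scenario truth to JSON (and back)
#'
#' @param scenario a [ScenarioTruth-class].
#' @param path output JSON path.
#' @return `writeScenario` invisibly returns `path`; `readScenario` returns
#'   the [ScenarioTruth-class].
#' @export
writeScenario <- function(scenario, path) {
  x <- list(psiTrue = scenario@psiTrue, pTrue = scenario@pTrue,
            DTrue = scenario@DTrue, detfunKey = scenario@detfunKey,
            detfunSigma = scenario@detfunSigma,
            detfunShape = scenario@detfunShape, aTrue = scenario@aTrue,
            activityWindows = scenario@activityWindows,
            nCameras = scenario@nCameras, deployDays = scenario@deployDays,
            theta = scenario@theta, w = scenario@w, t = scenario@t,
            seed = scenario@seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeScenario
#' @export
readScenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaultScenario(nCameras = x$nCameras, deployDays = x$deployDays,
                  theta = x$theta, w = x$w, t = x$t, DTrue = x$DTrue,
                  detfunKey = x$detfunKey, detfunSigma = x$detfunSigma,
                  detfunShape = if (is.null(x$detfunShape)) NA_real_
                                else x$detfunShape,
                  activityWindows = matrix(x$activityWindows,
                                           ncol = 2),
                  psiTrue = x$psiTrue, pTrue = x$pTrue, seed = x$seed)
}
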