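# S4 classes for the camera-trap analysis objects.

#' Detection history for one species
#'
#' A site-by-occasion matrix of daily detection (1), non-detection (0) and
#' missing effort (`NA`). Sites are camera locations; occasions are local
#' calendar days. This is the input to single-season occupancy estimation.
#'
#' @slot species scientific name of the focal species.
#' @slot sites character vector of location identifiers (rows).
#' @slot occasions `Date` vector of occasions (columns).
#' @slot matrix integer matrix, entries in \{0, 1, NA\}; `NA` means the
#'   camera at that site was not operational on that day.
#'
#' @seealso [buildDetectionHistory()], [fitOccupancy()]
#' @exportClass DetectionHistory
setClass("DetectionHistory",
  representation(species = "character", sites = "character",
                 occasions = "Date", matrix = "matrix"),
  validity = function(object) {
    m <- object@matrix
    if (nrow(m) != length(object@sites))
      return("matrix rows must match number of sites")
    if (ncol(m) != length(object@occasions))
      return("matrix columns must match number of occasions")
    v <- m[!is.na(m)]
    if (length(v) && !all(v %in% c(0L, 1L)))
      return("matrix entries must be 0, 1 or NA")
    TRUE
  })

#' Single-season occupancy model fit
#'
#' Result of maximising the zero-inflated binomial occupancy likelihood over
#' occupancy probability psi and detection probability p (constant or
#' per-occasion) on the logit scale.
#'
#' @slot psiHat estimated occupancy probability.
#' @slot pHat estimated detection probability; length 1 (constant) or T
#'   (time-varying).
#' @slot sePsi,seP delta-method standard errors (NA at a boundary).
#' @slot loglik maximised log-likelihood.
#' @slot converged optimizer convergence flag.
#' @slot boundary TRUE when the estimate sits on the parameter boundary, where
#'   the information-based standard errors are unreliable.
#' @slot nSites,nOccasions dimensions of the history.
#' @slot naiveOccupancy fraction of sites with at least one detection.
#' @slot pStructure "constant" or "time".
#' @exportClass OccupancyFit
setClass("OccupancyFit",
  representation(psiHat = "numeric", pHat = "numeric", sePsi = "numeric",
                 seP = "numeric", loglik = "numeric", converged = "logical",
                 boundary = "logical", nSites = "integer",
                 nOccasions = "integer", naiveOccupancy = "numeric",
                 pStructure = "character"),
  validity = function(object) {
    if (object@psiHat < 0 || object@psiHat > 1) return("psiHat outside [0,1]")
    if (any(object@pHat < 0 | object@pHat > 1)) return("pHat outside [0,1]")
    if (object@loglik > 1e-8) return("log-likelihood must be <= 0")
    TRUE
  })

#' Fitted point-transect detection function
#'
#' A key function (half-normal or hazard-rate) with up to two cosine
#' adjustment terms, fitted by maximum likelihood to radial observation
#' distances truncated at `w`.
#'
#' @slot key "half_normal" or "hazard_rate".
#' @slot sigma scale parameter (metres).
#' @slot shape hazard-rate shape b (>= 1); NA for half-normal.
#' @slot cosCoef cosine adjustment coefficients (0 to 2 of them).
#' @slot w truncation distance (metres).
#' @slot PHat average detection probability within w at a snapshot moment,
#'   i.e. the integral of g(x) 2x/w^2 over (0, w].
#' @slot loglik,aic,nParams fit summaries; aic = 2 nParams - 2 loglik.
#' @slot nObs number of observations used (after truncation).
#' @slot vcov parameter covariance matrix (inverse observed information) on
#'   the internal transformed scale; all-NA when unavailable.
#' @slot binned TRUE if fitted to binned distances.
#' @exportClass DetectionFunctionFit
setClass("DetectionFunctionFit",
  representation(key = "character", sigma = "numeric", shape = "numeric",
                 cosCoef = "numeric", w = "numeric", PHat = "numeric",
                 loglik = "numeric", aic = "numeric", nParams = "integer",
                 nObs = "integer", vcov = "matrix", binned = "logical"),
  validity = function(object) {
    if (!object@key %in% c("half_normal", "hazard_rate"))
      return("key must be half_normal or hazard_rate")
    if (object@sigma <= 0) return("sigma must be positive")
    if (!is.na(object@shape) && object@shape < 1) return("shape must be >= 1")
    if (length(object@cosCoef) > 2) return("at most two cosine adjustments")
    if (object@w <= 0) return("w must be positive")
    if (object@PHat <= 0 || object@PHat > 1 + 1e-9)
      return("PHat must lie in (0, 1]")
    if (abs(object@aic - (2 * object@nParams - 2 * object@loglik)) > 1e-6)
      return("aic inconsistent with loglik and nParams")
    TRUE
  })

#' AIC-weighted average of detection-function fits
#'
#' @slot fits list of [DetectionFunctionFit-class] members fitted to the same
#'   data and truncation distance.
#' @slot weights Akaike weights (sum to one).
#' @slot PBar weighted mean detection probability.
#' @slot cvP coefficient of variation of PBar (proportion), combining member
#'   sampling CVs with between-model spread.
#' @exportClass ModelAverage
setClass("ModelAverage",
  representation(fits = "list", weights = "numeric", PBar = "numeric",
                 cvP = "numeric"),
  validity = function(object) {
    if (length(object@fits) != length(object@weights))
      return("one weight per fit required")
    if (abs(sum(object@weights) - 1) > 1e-12)
      return("weights must sum to 1")
    P <- vapply(object@fits, function(f) f@PHat, numeric(1))
    if (length(P) && (object@PBar < min(P) - 1e-12 ||
                      object@PBar > max(P) + 1e-12))
      return("PBar must lie within the member PHat range")
    TRUE
  })

#' Encounter rate across cameras
#'
#' Mean number of observations per camera, with its variance estimated by the
#' effort-weighted between-camera estimator used in distance sampling.
#'
#' @slot counts per-camera observation counts n_k.
#' @slot efforts per-camera operational times T_k (seconds).
#' @slot epsilonBar mean encounter rate (observations per camera).
#' @slot varEpsilon estimated variance of epsilonBar.
#' @slot cvEpsilon coefficient of variation (proportion).
#' @exportClass EncounterRate
setClass("EncounterRate",
  representation(counts = "numeric", efforts = "numeric",
                 epsilonBar = "numeric", varEpsilon = "numeric",
                 cvEpsilon = "numeric"),
  validity = function(object) {
    if (length(object@counts) != length(object@efforts))
      return("counts and efforts must have equal length")
    if (any(object@efforts <= 0)) return("efforts must be positive")
    if (length(object@counts) < 2 && !is.na(object@varEpsilon))
      return("a variance requires at least two cameras")
    if (object@epsilonBar < 0 ||
        (!is.na(object@cvEpsilon) && object@cvEpsilon < 0))
      return("epsilonBar and cvEpsilon must be non-negative")
    TRUE
  })

#' Activity level (availability) estimate
#'
#' Proportion of time the species is active, estimated as
#' 1 / (2 pi max f) where f is a von Mises kernel density of observation
#' times of day on the circle.
#'
#' @slot a activity level in (0, 1].
#' @slot cvA bootstrap coefficient of variation (proportion; NA if not run).
#' @slot kappa kernel concentration parameter used.
#' @slot nTimes number of observation times.
#' @exportClass ActivityEstimate
setClass("ActivityEstimate",
  representation(a = "numeric", cvA = "numeric", kappa = "numeric",
                 nTimes = "integer"),
  validity = function(object) {
    if (object@a <= 0 || object@a > 1 + 1e-9) return("a must lie in (0, 1]")
    if (!is.na(object@cvA) && object@cvA < 0) return("cvA must be >= 0")
    TRUE
  })

#' Camera-trap distance-sampling density estimate
#'
#' Density per square kilometre computed from snapshot counts, effort, the
#' averaged detection probability and the activity level, with its CV composed
#' by the delta method.
#'
#' @slot DHat density (individuals per km^2).
#' @slot cvD delta-method coefficient of variation (proportion).
#' @slot t snapshot interval (seconds).
#' @slot theta horizontal angle of view (radians).
#' @slot w truncation distance (metres).
#' @slot encounter [EncounterRate-class] component.
#' @slot detection [ModelAverage-class] component.
#' @slot activity [ActivityEstimate-class] component.
#' @exportClass DensityEstimate
setClass("DensityEstimate",
  representation(DHat = "numeric", cvD = "numeric", t = "numeric",
                 theta = "numeric", w = "numeric", encounter = "EncounterRate",
                 detection = "ModelAverage", activity = "ActivityEstimate"),
  validity = function(object) {
    if (object@DHat < 0) return("DHat must be non-negative")
    comp <- c(object@encounter@cvEpsilon, object@detection@cvP,
              object@activity@cvA)
    comp <- comp[!is.na(comp)]
    if (length(comp) && object@cvD < max(comp) - 1e-9)
      return("cvD cannot be below its largest component")
    TRUE
  })

#' True parameters of a synthetic camera-trap scenario
#'
#' Carries everything the generator needs, and everything a recovery test
#' needs to know: true occupancy, detection, density, detection function,
#' activity schedule, camera grid geometry and the CTDS constants.
#'
#' @slot psiTrue,pTrue occupancy and per-occasion detection probability.
#' @slot DTrue density (individuals per km^2).
#' @slot detfunKey,detfunSigma,detfunShape true detection function.
#' @slot aTrue activity level; `activityWindows` is a 2-column matrix of
#'   active intervals in hours of day, total width 24 * aTrue.
#' @slot activityWindows matrix of active hour intervals.
#' @slot nCameras,deployDays camera grid size and deployment length.
#' @slot theta,w,t CTDS constants (radians, metres, seconds).
#' @slot seed integer generator seed.
#' @exportClass ScenarioTruth
setClass("ScenarioTruth",
  representation(psiTrue = "numeric", pTrue = "numeric", DTrue = "numeric",
                 detfunKey = "character", detfunSigma = "numeric",
                 detfunShape = "numeric", aTrue = "numeric",
                 activityWindows = "matrix", nCameras = "integer",
                 deployDays = "numeric", theta = "numeric", w = "numeric",
                 t = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@psiTrue < 0 || object@psiTrue > 1) return("psiTrue in [0,1]")
    if (object@pTrue < 0 || object@pTrue > 1) return("pTrue in [0,1]")
    if (object@DTrue < 0) return("DTrue must be >= 0")
    if (object@aTrue <= 0 || object@aTrue > 1) return("aTrue in (0,1]")
    if (object@theta <= 0 || object@theta >= 2 * pi)
      return("theta in (0, 2 pi)")
    if (object@w <= 0 || object@t <= 0) return("w and t must be positive")
    wid <- sum(object@activityWindows[, 2] - object@activityWindows[, 1])
    if (abs(wid / 24 - object@aTrue) > 1e-9)
      return("activityWindows width must equal 24 * aTrue hours")
    TRUE
  })

#' Survey effort summary
#'
#' @slot perDeployment named numeric, trap-days per deployment.
#' @slot perYear named numeric, trap-days per calendar year of deployment
#'   start.
#' @slot total grand total trap-days.
#' @exportClass EffortSummary
setClass("EffortSummary",
  representation(perDeployment = "numeric", perYear = "numeric",
                 total = "numeric"),
  validity = function(object) {
    relerr <- function(a, b) abs(a - b) / max(1, abs(b))
    if (relerr(sum(object@perDeployment), object@total) > 1e-9)
      return("total must equal the sum of per-deployment efforts")
    if (relerr(sum(object@perYear), object@total) > 1e-9)
      return("total must equal the sum of per-year efforts")
    TRUE
  })
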