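# Accessors and show() methods.

#' @name accessors
#' @title Accessor functions for camsnap objects
#' @description Small accessors so user code never touches slots directly.
#' @param object a camsnap S4 object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("detectionMatrix", function(object) standardGeneric("detectionMatrix"))
#' @rdname accessors
#' @export
setMethod("detectionMatrix", "DetectionHistory", function(object) object@matrix)

#' @rdname accessors
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setMethod("nSites", "DetectionHistory", function(object) length(object@sites))

#' @rdname accessors
#' @export
setGeneric("nOccasions", function(object) standardGeneric("nOccasions"))
#' @rdname accessors
#' @export
setMethod("nOccasions", "DetectionHistory", function(object) length(object@occasions))

#' Number of sites with at least one detection (n.)
#' @param object a [DetectionHistory-class].
#' @return integer count.
#' @export
setGeneric("nDot", function(object) standardGeneric("nDot"))
#' @rdname nDot
#' @export
setMethod("nDot", "DetectionHistory", function(object)
  sum(apply(object@matrix, 1, function(r) any(r == 1, na.rm = TRUE))))

#' Per-occasion detection counts (n_t)
#' @param object a [DetectionHistory-class].
#' @return integer vector, one entry per occasion.
#' @export
setGeneric("nPerOccasion", function(object) standardGeneric("nPerOccasion"))
#' @rdname nPerOccasion
#' @export
setMethod("nPerOccasion", "DetectionHistory", function(object)
  unname(apply(object@matrix, 2, function(col) sum(col == 1, na.rm = TRUE))))

#' Naive occupancy: detected sites / all sites
#' @param object a [DetectionHistory-class] or [OccupancyFit-class].
#' @return numeric proportion.
#' @export
setGeneric("naiveOccupancy", function(object) standardGeneric("naiveOccupancy"))
#' @rdname naiveOccupancy
#' @export
setMethod("naiveOccupancy", "DetectionHistory", function(object)
  nDot(object) / length(object@sites))
#' @rdname naiveOccupancy
#' @export
setMethod("naiveOccupancy", "OccupancyFit", function(object) object@naiveOccupancy)

#' @rdname accessors
#' @export
setGeneric("psiHat", function(object) standardGeneric("psiHat"))
#' @rdname accessors
#' @export
setMethod("psiHat", "OccupancyFit", function(object) object@psiHat)

#' @rdname accessors
#' @export
setGeneric("pHat", function(object) standardGeneric("pHat"))
#' @rdname accessors
#' @export
setMethod("pHat", "OccupancyFit", function(object) object@pHat)

#' @rdname accessors
#' @export
setGeneric("PHat", function(object) standardGeneric("PHat"))
#' @rdname accessors
#' @export
setMethod("PHat", "DetectionFunctionFit", function(object) object@PHat)
#' @rdname accessors
#' @export
setMethod("PHat", "ModelAverage", function(object) object@PBar)

#' @rdname accessors
#' @export
setGeneric("modelAIC", function(object) standardGeneric("modelAIC"))
#' @rdname accessors
#' @export
setMethod("modelAIC", "DetectionFunctionFit", function(object) object@aic)

#' @rdname accessors
#' @export
setGeneric("akaikeWeights", function(object) standardGeneric("akaikeWeights"))
#' @rdname accessors
#' @export
setMethod("akaikeWeights", "ModelAverage", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("activityLevel", function(object) standardGeneric("activityLevel"))
#' @rdname accessors
#' @export
setMethod("activityLevel", "ActivityEstimate", function(object) object@a)

#' @rdname accessors
#' @export
setGeneric("densityPerKm2", function(object) standardGeneric("densityPerKm2"))
#' @rdname accessors
#' @export
setMethod("densityPerKm2", "DensityEstimate", function(object) object@DHat)

#' @rdname accessors
#' @export
setGeneric("cv", function(object) standardGeneric("cv"))
#' @rdname accessors
#' @export
setMethod("cv", "DensityEstimate", function(object) object@cvD)
#' @rdname accessors
#' @export
setMethod("cv", "EncounterRate", function(object) object@cvEpsilon)
#' @rdname accessors
#' @export
setMethod("cv", "ModelAverage", function(object) object@cvP)
#' @rdname accessors
#' @export
setMethod("cv", "ActivityEstimate", function(object) object@cvA)

#' @rdname accessors
#' @export
setGeneric("totalEffort", function(object) standardGeneric("totalEffort"))
#' @rdname accessors
#' @export
setMethod("totalEffort", "EffortSummary", function(object) object@total)
#' @rdname accessors
#' @export
setGeneric("effortPerYear", function(object) standardGeneric("effortPerYear"))
#' @rdname accessors
#' @export
setMethod("effortPerYear", "EffortSummary", function(object) object@perYear)
#' @rdname accessors
#' @export
setGeneric("effortPerDeployment", function(object) standardGeneric("effortPerDeployment"))
#' @rdname accessors
#' @export
setMethod("effortPerDeployment", "EffortSummary", function(object) object@perDeployment)

setMethod("show", "DetectionHistory", function(object) {
  cat("DetectionHistory:", object@species, "\n")
  cat(sprintf("  %d sites x %d occasions (%s .. %s)\n", nSites(object),
              nOccasions(object), min(object@occasions), max(object@occasions)))
  cat(sprintf("  n. = %d detected sites, naive occupancy = %.3f, %.1f%% missing\n",
              nDot(object), naiveOccupancy(object),
              100 * mean(is.na(object@matrix))))
})

setMethod("show", "OccupancyFit", function(object) {
  cat("Single-season occupancy fit (", object@pStructure, " p)\n", sep = "")
  cat(sprintf("  psi = %.4f (SE %.4f)\n", object@psiHat, object@sePsi))
  if (length(object@pHat) == 1L)
    cat(sprintf("  p   = %.4f (SE %.4f)\n", object@pHat, object@seP))
  else
    cat(sprintf("  p_t in [%.4f, %.4f]\n", min(object@pHat), max(object@pHat)))
  cat(sprintf("  logLik = %.4f, N = %d, T = %d, naive = %.3f%s%s\n",
              object@loglik, object@nSites, object@nOccasions,
              object@naiveOccupancy,
              if (!object@converged) ", NOT converged" else "",
              if (object@boundary) ", boundary" else ""))
})

setMethod("show", "DetectionFunctionFit", function(object) {
  cat(sprintf("Detection function: %s%s, %d cosine adjustment(s)\n",
              object@key, if (object@binned) " (binned)" else "",
              length(object@cosCoef)))
  cat(sprintf("  sigma = %.3f m%s, w = %.1f m\n", object@sigma,
              if (!is.na(object@shape)) sprintf(", b = %.3f", object@shape) else "",
              object@w))
  cat(sprintf("  P = %.4f, logLik = %.3f, AIC = %.3f (n = %d)\n",
              object@PHat, object@loglik, object@aic, object@nObs))
})

setMethod("show", "ModelAverage", function(object) {
  cat(sprintf("Model average of %d detection function(s)\n", length(object@fits)))
  for (i in seq_along(object@fits)) {
    f <- object@fits[[i]]
    cat(sprintf("  %-12s adj=%d  AIC=%9.3f  w=%.3f  P=%.4f\n", f@key,
                length(f@cosCoef), f@aic, object@weights[i], f@PHat))
  }
  cat(sprintf("  P(avg) = %.4f, CV = %.1f%%\n", object@PBar, 100 * object@cvP))
})

setMethod("show", "EncounterRate", function(object) {
  cat(sprintf("Encounter rate: %.4f obs/camera over %d cameras (CV %.1f%%)\n",
              object@epsilonBar, length(object@counts), 100 * object@cvEpsilon))
})

setMethod("show", "ActivityEstimate", function(object) {
  cat(sprintf("Activity level a = %.3f (CV %s) from %d times, kappa = %.2f\n",
              object@a,
              if (is.na(object@cvA)) "not estimated"
              else sprintf("%.1f%%", 100 * object@cvA),
              object@nTimes, object@kappa))
})

setMethod("show", "DensityEstimate", function(object) {
  cat(sprintf("CTDS density: %.3f individuals / km^2 (CV %.1f%%)\n",
              object@DHat, 100 * object@cvD))
  cat(sprintf("  t = %g s, theta = %g rad, w = %g m, a = %.3f, P = %.4f, eps = %.4f\n",
              object@t, object@theta, object@w, object@activity@a,
              object@detection@PBar, object@encounter@epsilonBar))
})

setMethod("show", "EffortSummary", function(object) {
  cat(sprintf("Effort: %.1f trap-days over %d deployments\n", object@total,
              length(object@perDeployment)))
  for (y in names(object@perYear))
    cat(sprintf("  %s: %.1f\n", y, object@perYear[[y]]))
})

setMethod("show", "ScenarioTruth", function(object) {
  cat("Synthetic camera-trap scenario truth\n")
  cat(sprintf("  %d cameras x %.0f days; t = %g s, theta = %g rad, w = %g m\n",
              object@nCameras, object@deployDays, object@t, object@theta, object@w))
  cat(sprintf("  D = %g /km^2, a = %g, psi = %g, p = %g, detfun = %s(sigma=%g%s)\n",
              object@DTrue, object@aTrue, object@psiTrue, object@pTrue,
              object@detfunKey, object@detfunSigma,
              if (!is.na(object@detfunShape)) sprintf(", b=%g", object@detfunShape) else ""))
})
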