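# Encounter rate, CTDS density, delta-method CV composition, bootstrap CV.

#' Encounter rate and its between-camera variance
#'
#' The mean encounter rate is the number of observations per camera,
#' `epsilonBar = sum(n_k) / K`. Its variance uses the effort-weighted
#' between-camera estimator familiar from distance sampling:
#' \deqn{\widehat{var} = \frac{K}{K-1} \frac{1}{K^2} \sum_k
#'   \left(\frac{T_k}{\bar T}\right)^2
#'   \left(\frac{n_k}{T_k}\bar T - \bar\varepsilon\right)^2}
#' with \eqn{\bar T = \sum_k T_k / K}. Under equal effort this reduces to the
#' usual between-camera variance of the mean.
#'
#' @param counts per-camera observation counts `n_k` (length K >= 2).
#' @param efforts per-camera operational times `T_k` (positive; any common
#'   unit).
#' @return an [EncounterRate-class].
#' @export
encounterRate <- function(counts, efforts) {
  K <- length(counts)
  if (K < 2) stop("at least two cameras are required for a variance",
                  call. = FALSE)
  if (length(efforts) != K)
    stop("counts and efforts must have equal length", call. = FALSE)
  if (any(efforts <= 0)) stop("efforts must be positive", call. = FALSE)
  if (all(counts == 0))
    stop("all camera counts are zero: encounter-rate CV undefined",
         call. = FALSE)
  Tbar <- mean(efforts)
  eps <- sum(counts) / K
  rate <- counts / efforts * Tbar   # counts standardised to mean effort
  v <- (K / (K - 1)) * sum((efforts / Tbar)^2 * (rate - eps)^2) / K^2
  methods::new("EncounterRate", counts = as.numeric(counts),
               efforts = as.numeric(efforts), epsilonBar = eps,
               varEpsilon = v, cvEpsilon = sqrt(v) / eps)
}

#' Delta-method CV composition
#'
#' Combines independent component coefficients of variation into the CV of
#' the density estimate: `cv_D = sqrt(cv_eps^2 + cv_p^2 + cv_a^2)`.
#' Scale-agnostic: feed proportions to get a proportion, percentages to get
#' a percentage.
#'
#' @param cvEpsilon,cvP,cvA non-negative component CVs.
#' @return the composed CV, same scale as the inputs.
#' @examples
#' deltaCV(16, 4, 8)   # 18.33 -> prints as 18%
#' @export
deltaCV <- function(cvEpsilon, cvP, cvA) {
  if (any(c(cvEpsilon, cvP, cvA) < 0))
    stop("component CVs must be non-negative", call. = FALSE)
  sqrt(cvEpsilon^2 + cvP^2 + cvA^2)
}

#' Camera-trap distance-sampling density estimate
#'
#' Implements the snapshot-moment density estimator
#' \deqn{\hat D = \frac{2 t \sum_k n_k}{\theta w^2 a \sum_k T_k \hat P}}
#' where `t` is the snapshot interval, `theta` the camera's horizontal angle
#' of view, `w` the truncation distance, `n_k` the snapshot observations at
#' camera k, `T_k` its operational time and `P` the (model-averaged)
#' probability of detecting an available animal within `w`. The activity
#' level `a` scales the effort down to the time animals are available, so
#' halving `a` doubles the estimate. Internally per square metre; reported
#' per square kilometre.
#'
#' @param counts per-camera snapshot observation counts `n_k`.
#' @param efforts per-camera operational times `T_k` in seconds.
#' @param detection a [ModelAverage-class] (or single
#'   [DetectionFunctionFit-class], treated as a one-member average).
#' @param activity an [ActivityEstimate-class].
#' @param t snapshot interval in seconds.
#' @param theta horizontal angle of view in radians.
#' @param w truncation distance in metres (must match the detection fits).
#' @return a [DensityEstimate-class]; its CV composes the encounter-rate,
#'   detection and activity CVs by [deltaCV()].
#' @export
estimateDensity <- function(counts, efforts, detection, activity,
                            t, theta, w) {
  if (t <= 0) stop("snapshot interval t must be positive", call. = FALSE)
  if (theta <= 0 || theta >= 2 * pi)
    stop("theta must lie in (0, 2*pi)", call. = FALSE)
  if (methods::is(detection, "DetectionFunctionFit"))
    detection <- modelAverage(list(detection))
  if (abs(detection@fits[[1]]@w - w) > 1e-9)
    stop("w disagrees with the detection-function truncation distance",
         call. = FALSE)
  a <- activity@a
  if (a <= 0) stop("activity level a must be positive", call. = FALSE)
  if (sum(efforts) <= 0) stop("total effort is zero", call. = FALSE)

  enc <- if (length(counts) >= 2) encounterRate(counts, efforts)
  else methods::new("EncounterRate", counts = as.numeric(counts),
                    efforts = as.numeric(efforts),
                    epsilonBar = sum(counts), varEpsilon = NA_real_,
                    cvEpsilon = NA_real_)
  PBar <- detection@PBar
  DperM2 <- 2 * t * sum(counts) / (theta * w^2 * a * sum(efforts * PBar))
  naZero <- function(x) if (is.na(x)) 0 else x
  cvD <- deltaCV(naZero(enc@cvEpsilon), naZero(detection@cvP),
                 naZero(activity@cvA))
  methods::new("DensityEstimate", DHat = DperM2 * 1e6, cvD = cvD,
               t = t, theta = theta, w = w, encounter = enc,
               detection = detection, activity = activity)
}

#' Nonparametric bootstrap coefficient of variation
#'
#' Resamples the observations with replacement `B` times, re-runs the
#' estimator, and returns sd/mean of the bootstrap estimates. Deterministic
#' for a fixed `seed`; the caller's RNG state is left untouched.
#'
#' @param data vector (or data.frame, resampled by row) of observations.
#' @param estimator function mapping a resample to a single number.
#' @param B number of bootstrap iterations (default 999).
#' @param seed optional integer seed.
#' @return the bootstrap CV (sd/mean, a proportion), with the bootstrap
#'   estimates attached as attribute `"estimates"`.
#' @export
bootstrapCv <- function(data, estimator, B = 999, seed = NULL) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n == 0) stop("data is empty", call. = FALSE)
  pick <- if (is.data.frame(data))
    function(idx) data[idx, , drop = FALSE] else function(idx) data[idx]
  est <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(as.numeric(estimator(pick(idx))),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  failed <- mean(is.na(est))
  if (failed > 0.2)
    stop(sprintf("estimator failed on %.0f%% of bootstrap resamples",
                 100 * failed), call. = FALSE)
  est <- est[!is.na(est)]
  out <- stats::sd(est) / mean(est)
  attr(out, "estimates") <- est
  out
}
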