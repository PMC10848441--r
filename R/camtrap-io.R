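# Reading and writing camera-trap tables (Camtrap DP and Darwin Core Archive),
# sequence grouping, effort and tally summaries.
#
# The internal model is a pair of plain data.frames:
#   deployments: deploymentID, locationID, latitude, longitude,
#                start, end (POSIXct UTC), sensitivity, cameraAngle
#   occurrences: occurrenceID, deploymentID, timestamp (POSIXct UTC),
#                taxon ("blank"/"unknown" sentinels allowed),
#                observationType, nImages, distances (";"-separated metres,
#                "" if unmeasured), isFirstTrigger

TAXON_SENTINELS <- c("blank", "unknown")

DEPLOYMENT_COLUMNS <- c("deploymentID", "locationID", "longitude", "latitude",
                        "start", "end")
OBSERVATION_COLUMNS <- c("observationID", "deploymentID", "sequenceID",
                         "timestamp", "observationType", "scientificName")

#' @noRd
validateDeployments <- function(dep) {
  bad <- which(dep$end <= dep$start)
  if (length(bad))
    stop("deployment(s) with end <= start at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(dep$latitude < -90 | dep$latitude > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(dep$longitude < -180 | dep$longitude > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]", call. = FALSE)
  invisible(dep)
}

#' @noRd
checkReferentialIntegrity <- function(occ, dep) {
  unknown <- setdiff(unique(occ$deploymentID), dep$deploymentID)
  if (length(unknown))
    stop("observation(s) reference unknown deploymentID(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' @noRd
parseTimestampColumn <- function(x, what) {
  out <- parseIso8601(x)
  bad <- which(is.na(out) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad))
    stop(sprintf("%s: unparseable timestamp at row(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  out
}

#' @noRd
mapTaxon <- function(observationType, scientificName) {
  type <- tolower(trimws(as.character(observationType)))
  taxon <- trimws(as.character(scientificName))
  taxon[type == "blank"] <- "blank"
  taxon[type %in% c("unknown", "unclassified")] <- "unknown"
  taxon[type == "animal" & !nzchar(taxon)] <- "unknown"
  taxon
}

#' Split a ";"-separated distance field into numeric metres
#'
#' @param x character vector as stored in the `distances` column.
#' @return list of numeric vectors (possibly empty).
#' @export
parseDistances <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Read a Camtrap DP deployment/observation table pair
#'
#' Parses the two CSV tables of a Camtrap DP package into the internal model.
#' `observationType` drives the taxon sentinel mapping: rows typed `blank`
#' become the sentinel `"blank"`, rows typed `unknown`/`unclassified` become
#' `"unknown"`; only `animal` rows carry a scientific name.
#'
#' @param deploymentsPath path to `deployments.csv`.
#' @param observationsPath path to `observations.csv`.
#' @return list with elements `deployments` and `occurrences` (data.frames).
#' @examples
#' d <- system.file("extdata", "camtrapdp_deployments_example.csv", package = "camsnap")
#' o <- system.file("extdata", "camtrapdp_observations_example.csv", package = "camsnap")
#' x <- readCamtrapDP(d, o)
#' nrow(x$deployments); nrow(x$occurrences)
#' @export
readCamtrapDP <- function(deploymentsPath, observationsPath) {
  depRaw <- utils::read.csv(deploymentsPath, stringsAsFactors = FALSE,
                            colClasses = "character")
  obsRaw <- utils::read.csv(observationsPath, stringsAsFactors = FALSE,
                            colClasses = "character")
  stopIfMissingColumns(depRaw, DEPLOYMENT_COLUMNS, "deployments")
  stopIfMissingColumns(obsRaw, OBSERVATION_COLUMNS, "observations")

  dep <- data.frame(
    deploymentID = depRaw$deploymentID,
    locationID   = depRaw$locationID,
    latitude     = as.numeric(depRaw$latitude),
    longitude    = as.numeric(depRaw$longitude),
    start = parseTimestampColumn(depRaw$start, "deployments$start"),
    end   = parseTimestampColumn(depRaw$end, "deployments$end"),
    sensitivity = if ("sensitivity" %in% names(depRaw))
      depRaw$sensitivity else "unknown",
    cameraAngle = if ("cameraAngle" %in% names(depRaw))
      as.numeric(depRaw$cameraAngle) else NA_real_,
    stringsAsFactors = FALSE)
  validateDeployments(dep)

  occ <- data.frame(
    occurrenceID = obsRaw$sequenceID,
    deploymentID = obsRaw$deploymentID,
    timestamp = parseTimestampColumn(obsRaw$timestamp, "observations$timestamp"),
    taxon = mapTaxon(obsRaw$observationType, obsRaw$scientificName),
    observationType = tolower(trimws(obsRaw$observationType)),
    nImages = if ("nImages" %in% names(obsRaw))
      as.integer(obsRaw$nImages) else 1L,
    distances = if ("distances" %in% names(obsRaw))
      as.character(obsRaw$distances) else "",
    isFirstTrigger = if ("isFirstTrigger" %in% names(obsRaw))
      as.logical(obsRaw$isFirstTrigger) else TRUE,
    stringsAsFactors = FALSE)
  occ$distances[is.na(occ$distances)] <- ""
  if (any(occ$nImages < 1, na.rm = TRUE))
    stop("nImages must be >= 1", call. = FALSE)
  checkReferentialIntegrity(occ, dep)
  list(deployments = dep, occurrences = occ)
}

#' Write the internal model as a Camtrap DP table pair
#'
#' Emits `deployments.csv` and `observations.csv` with the standard column
#' sets (plus the `nImages`, `distances` and `isFirstTrigger` extension
#' columns) such that [readCamtrapDP()] recovers the input exactly.
#'
#' @param deployments,occurrences internal-model data.frames.
#' @param outDir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writeCamtrapDP <- function(deployments, occurrences, outDir) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  depFile <- file.path(outDir, "deployments.csv")
  obsFile <- file.path(outDir, "observations.csv")

  depOut <- data.frame(
    deploymentID = deployments$deploymentID,
    locationID   = deployments$locationID,
    longitude    = deployments$longitude,
    latitude     = deployments$latitude,
    start = formatIso8601Utc(deployments$start),
    end   = formatIso8601Utc(deployments$end),
    sensitivity = deployments$sensitivity,
    cameraAngle = deployments$cameraAngle,
    stringsAsFactors = FALSE)

  type <- occurrences$observationType
  sci <- ifelse(occurrences$taxon %in% TAXON_SENTINELS, "", occurrences$taxon)
  obsOut <- data.frame(
    observationID = sprintf("obs_%d", seq_len(nrow(occurrences))),
    deploymentID = occurrences$deploymentID,
    sequenceID = occurrences$occurrenceID,
    timestamp = formatIso8601Utc(occurrences$timestamp),
    observationType = type,
    scientificName = sci,
    nImages = occurrences$nImages,
    distances = occurrences$distances,
    isFirstTrigger = occurrences$isFirstTrigger,
    stringsAsFactors = FALSE)

  utils::write.csv(depOut, depFile, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  utils::write.csv(obsOut, obsFile, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(c(deployments = depFile, observations = obsFile))
}

#' Read a Darwin Core Archive event/occurrence table pair
#'
#' Sampling-event datasets model a camera deployment as an Event whose
#' `eventDate` is an ISO 8601 interval (`start/end`), and each species record
#' as an Occurrence linked by `eventID`. Open-ended intervals are rejected.
#' When `sampleSizeValue` (trap-nights) disagrees with the effort recomputed
#' from the interval by more than half a day, a warning is raised and the
#' recomputed value is used.
#'
#' @param eventsPath path to the event CSV table.
#' @param occurrencesPath path to the occurrence CSV table.
#' @return list with elements `deployments` and `occurrences`, same internal
#'   model as [readCamtrapDP()].
#' @export
readDwcArchive <- function(eventsPath, occurrencesPath) {
  evRaw <- utils::read.csv(eventsPath, stringsAsFactors = FALSE,
                           colClasses = "character")
  ocRaw <- utils::read.csv(occurrencesPath, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopIfMissingColumns(evRaw, c("eventID", "decimalLatitude",
                                "decimalLongitude", "eventDate"), "events")
  stopIfMissingColumns(ocRaw, c("occurrenceID", "eventID", "scientificName"),
                       "occurrences")

  parts <- strsplit(as.character(evRaw$eventDate), "/", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L |
                 vapply(parts, function(p) any(!nzchar(p)), logical(1)))
  if (length(bad))
    stop("events$eventDate: expected a closed 'start/end' ISO interval at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  start <- parseTimestampColumn(vapply(parts, `[`, character(1), 1),
                                "events$eventDate start")
  end <- parseTimestampColumn(vapply(parts, `[`, character(1), 2),
                              "events$eventDate end")
  badOrder <- which(end <= start)
  if (length(badOrder))
    stop("events$eventDate: interval end before start at row(s): ",
         paste(badOrder, collapse = ", "), call. = FALSE)

  dep <- data.frame(
    deploymentID = evRaw$eventID,
    locationID = if ("locationID" %in% names(evRaw))
      evRaw$locationID else evRaw$eventID,
    latitude = as.numeric(evRaw$decimalLatitude),
    longitude = as.numeric(evRaw$decimalLongitude),
    start = start, end = end,
    sensitivity = "unknown",
    cameraAngle = NA_real_,
    stringsAsFactors = FALSE)
  validateDeployments(dep)

  if ("sampleSizeValue" %in% names(evRaw)) {
    stated <- as.numeric(evRaw$sampleSizeValue)
    recomputed <- as.numeric(difftime(end, start, units = "days"))
    off <- which(!is.na(stated) & abs(stated - recomputed) > 0.5)
    if (length(off))
      warning("sampleSizeValue disagrees with the eventDate interval by ",
              "more than 0.5 trap-days at row(s) ",
              paste(off, collapse = ", "),
              "; using the recomputed effort", call. = FALSE)
  }

  # occurrence timestamp: full ISO in eventDate, or eventDate + eventTime
  ts <- as.character(ocRaw$eventDate)
  if ("eventTime" %in% names(ocRaw)) {
    noTime <- !grepl("T", ts, fixed = TRUE) & nzchar(as.character(ocRaw$eventTime))
    ts[noTime] <- paste0(ts[noTime], "T", ocRaw$eventTime[noTime])
  }
  occ <- data.frame(
    occurrenceID = ocRaw$occurrenceID,
    deploymentID = ocRaw$eventID,
    timestamp = parseTimestampColumn(ts, "occurrences$eventDate"),
    taxon = trimws(ocRaw$scientificName),
    observationType = "animal",
    nImages = if ("individualCount" %in% names(ocRaw))
      pmax(1L, as.integer(ocRaw$individualCount)) else 1L,
    distances = "",
    isFirstTrigger = TRUE,
    stringsAsFactors = FALSE)
  checkReferentialIntegrity(occ, dep)
  list(deployments = dep, occurrences = occ)
}

#' Group images into occurrence sequences
#'
#' Within a deployment, two consecutive images belong to the same sequence
#' when their timestamps differ by at most `gapSeconds` (single-linkage
#' chaining in time). Each resulting sequence is one occurrence event: its
#' timestamp is the first image's timestamp and `nImages` its size.
#'
#' @param media data.frame with columns `mediaID`, `deploymentID`,
#'   `timestamp` (POSIXct); input order is irrelevant.
#' @param gapSeconds positive gap threshold in seconds (default 120).
#' @return data.frame of sequence skeletons: `occurrenceID`, `deploymentID`,
#'   `timestamp`, `nImages`, plus a `mediaIDs` ";"-separated bookkeeping
#'   column. The partition of the input is exhaustive and disjoint.
#' @export
groupIntoSequences <- function(media, gapSeconds = 120) {
  if (gapSeconds <= 0) stop("gapSeconds must be positive", call. = FALSE)
  if (nrow(media) == 0)
    return(data.frame(occurrenceID = character(0), deploymentID = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      nImages = integer(0), mediaIDs = character(0),
                      stringsAsFactors = FALSE))
  ord <- order(media$deploymentID, media$timestamp)
  m <- media[ord, , drop = FALSE]
  dt <- c(Inf, diff(as.numeric(m$timestamp)))
  newDep <- c(TRUE, m$deploymentID[-1] != m$deploymentID[-nrow(m)])
  newSeq <- newDep | dt > gapSeconds
  seqId <- cumsum(newSeq)
  first <- !duplicated(seqId)
  data.frame(
    occurrenceID = paste0("seq_", m$deploymentID[first], "_",
                          ave(seqId[first], m$deploymentID[first],
                              FUN = seq_along)),
    deploymentID = m$deploymentID[first],
    timestamp = m$timestamp[first],
    nImages = as.integer(tabulate(seqId)),
    mediaIDs = vapply(split(as.character(m$mediaID), seqId),
                      paste, character(1), collapse = ";"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarise sampling effort in trap-days
#'
#' Effort is the number of cameras multiplied by the number of days each
#' remained active: per deployment, `(end - start)` in fractional days.
#'
#' @param deployments internal-model deployment data.frame.
#' @return an [EffortSummary-class] with per-deployment, per-year (year of
#'   deployment start) and total trap-days.
#' @export
effortSummary <- function(deployments) {
  validateDeployments(deployments)
  days <- as.numeric(difftime(deployments$end, deployments$start,
                              units = "days"))
  names(days) <- deployments$deploymentID
  year <- format(deployments$start, "%Y", tz = "UTC")
  perYear <- tapply(days, year, sum)
  methods::new("EffortSummary", perDeployment = days,
               perYear = stats::setNames(as.numeric(perYear), names(perYear)),
               total = sum(days))
}

#' Tally occurrence sequences by species (and year)
#'
#' Counts occurrence events per species, optionally split by calendar year.
#' Sentinel taxa (`blank`, `unknown`) are excluded from the species rows and
#' reported separately in the `"sentinels"` attribute.
#'
#' @param occurrences internal-model occurrence data.frame.
#' @param by `"species"` for totals only, or `c("species", "year")`.
#' @return data.frame with one row per species, yearly columns when
#'   requested, and a `total` column; `attr(, "sentinels")` holds the
#'   excluded sentinel counts.
#' @export
speciesTally <- function(occurrences, by = c("species", "year")) {
  by <- match.arg(by, c("species", "year"), several.ok = TRUE)
  isSent <- occurrences$taxon %in% TAXON_SENTINELS
  sentinels <- table(factor(occurrences$taxon[isSent], levels = TAXON_SENTINELS))
  occ <- occurrences[!isSent, , drop = FALSE]
  if (nrow(occ) == 0) {
    out <- data.frame(species = character(0), total = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "sentinels") <- sentinels
    return(out)
  }
  if ("year" %in% by) {
    year <- format(occ$timestamp, "%Y", tz = "UTC")
    tab <- table(occ$taxon, year)
    out <- data.frame(species = rownames(tab),
                      as.data.frame.matrix(tab),
                      total = as.integer(rowSums(tab)),
                      row.names = NULL, check.names = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    tab <- table(occ$taxon)
    out <- data.frame(species = names(tab), total = as.integer(tab),
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- out[order(-out$total, out$species), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sentinels") <- sentinels
  out
}
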