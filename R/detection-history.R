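# Detection histories: species x site x day matrices for occupancy.

#' Build a daily detection history for one species
#'
#' Converts occurrences and deployments into a site-by-occasion matrix of
#' presence/absence records: one record per species, camera location and
#' local calendar day. A cell is 1 when the species was recorded at that site
#' that day, 0 when a camera was operational there but nothing was recorded,
#' and `NA` when no camera was operational. A partial first or last day
#' counts as an occasion if the camera ran at least one second of it.
#' Multiple deployments sharing a `locationID` are unioned into one site row.
#'
#' @param occurrences,deployments internal-model data.frames (see
#'   [readCamtrapDP()]).
#' @param species focal scientific name; a species absent from the data
#'   yields a valid all-zero history.
#' @param occasionDays occasion length in days (default 1; larger values
#'   collapse consecutive days, a cell being 1 if any member day is 1).
#' @param tzOffset local-time UTC offset used to define the calendar day
#'   (default `"+01:00"`).
#' @return a [DetectionHistory-class].
#' @export
buildDetectionHistory <- function(occurrences, deployments, species,
                                  occasionDays = 1, tzOffset = "+01:00") {
  validateDeployments(deployments)
  if (nrow(deployments) == 0) stop("empty history: no deployments",
                                   call. = FALSE)
  offSec <- offsetSeconds(tzOffset)
  depStartDay <- localDay(deployments$start, tzOffset)
  depEndDay <- localDay(deployments$end - 1e-6, tzOffset)
  days <- seq(min(depStartDay), max(depEndDay), by = "day")
  sites <- sort(unique(deployments$locationID))
  N <- length(sites); nd <- length(days)

  op <- matrix(FALSE, N, nd, dimnames = list(sites, as.character(days)))
  for (i in seq_len(nrow(deployments))) {
    r <- match(deployments$locationID[i], sites)
    cols <- which(days >= depStartDay[i] & days <= depEndDay[i])
    op[r, cols] <- TRUE
  }
  if (!any(op)) stop("empty history: no operational days", call. = FALSE)

  m <- matrix(NA_integer_, N, nd, dimnames = dimnames(op))
  m[op] <- 0L

  occ <- occurrences[occurrences$taxon == species, , drop = FALSE]
  if (nrow(occ)) {
    checkReferentialIntegrity(occ, deployments)
    loc <- deployments$locationID[match(occ$deploymentID,
                                        deployments$deploymentID)]
    day <- localDay(occ$timestamp, tzOffset)
    r <- match(loc, sites)
    cols <- match(as.character(day), as.character(days))
    keep <- !is.na(cols)
    m[cbind(r[keep], cols[keep])] <- 1L
  }

  if (occasionDays > 1) {
    grp <- (seq_len(nd) - 1) %/% occasionDays
    collapsed <- sapply(split(seq_len(nd), grp), function(cols) {
      sub <- m[, cols, drop = FALSE]
      apply(sub, 1, function(r) {
        if (all(is.na(r))) NA_integer_ else as.integer(any(r == 1, na.rm = TRUE))
      })
    })
    if (N == 1) collapsed <- matrix(collapsed, nrow = 1)
    m <- collapsed
    days <- days[!duplicated(grp)]
    dimnames(m) <- list(sites, as.character(days))
  }

  methods::new("DetectionHistory", species = species, sites = sites,
               occasions = days, matrix = m)
}

#' Export a detection history as wide CSV
#'
#' One row per site, one column per occasion, cells 0/1/NA — the layout
#' occupancy software expects.
#'
#' @param history a [DetectionHistory-class].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeDetectionHistory <- function(history, path) {
  df <- data.frame(site = history@sites, history@matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct a DetectionHistory from a matrix
#'
#' Convenience constructor used by the simulator and in tests.
#'
#' @param m integer matrix with entries 0/1/NA.
#' @param species species label.
#' @param startDay first occasion date.
#' @return a [DetectionHistory-class].
#' @export
detectionHistoryFromMatrix <- function(m, species = "synthetic",
                                       startDay = as.Date("2019-05-07")) {
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  sites <- sprintf("site_%03d", seq_len(nrow(m)))
  days <- seq(startDay, by = "day", length.out = ncol(m))
  dimnames(m) <- list(sites, as.character(days))
  methods::new("DetectionHistory", species = species, sites = sites,
               occasions = days, matrix = m)
}
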