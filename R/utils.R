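# Internal helpers: ISO 8601 timestamps, timezone offsets, seeded evaluation.

#' Parse ISO 8601 timestamps with timezone designator
#'
#' Accepts `YYYY-MM-DDThh:mm:ssZ` and `YYYY-MM-DDThh:mm:ss+hh:mm` (or `+hhmm`)
#' forms and returns POSIXct in UTC. Values that fail to parse come back `NA`.
#'
#' @param x character vector of timestamps.
#' @return POSIXct vector (UTC).
#' @keywords internal
#' @noRd
parseIso8601 <- function(x) {
  x <- as.character(x)
  y <- sub("Z$", "+0000", x)
  # strip the colon inside a numeric offset (+01:00 -> +0100)
  y <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", y)
  out <- as.POSIXct(strptime(y, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC"))
  # date-only fallback (midnight UTC)
  bare <- is.na(out) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  if (any(bare))
    out[bare] <- as.POSIXct(x[bare], tz = "UTC")
  out
}

#' @noRd
formatIso8601Utc <- function(x) {
  format(as.POSIXct(x, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Convert a "+hh:mm" UTC offset string to seconds
#' @noRd
offsetSeconds <- function(offset) {
  if (is.numeric(offset)) return(offset * 3600)
  m <- regmatches(offset, regexec("^([+-])([0-9]{2}):?([0-9]{2})$", offset))[[1]]
  if (length(m) != 4)
    stop("invalid timezone offset: ", offset, call. = FALSE)
  sgn <- if (m[2] == "-") -1 else 1
  sgn * (as.numeric(m[3]) * 3600 + as.numeric(m[4]) * 60)
}

#' Local calendar day of a UTC timestamp under a fixed offset
#' @noRd
localDay <- function(time, offset = "+01:00") {
  as.Date(as.POSIXct(time, tz = "UTC") + offsetSeconds(offset), tz = "UTC")
}

#' Local time of day in radians [0, 2*pi)
#' @noRd
localTimeRadians <- function(time, offset = "+01:00") {
  t <- as.POSIXct(time, tz = "UTC") + offsetSeconds(offset)
  sec <- as.numeric(t) %% 86400
  sec / 86400 * 2 * pi
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded operations do not
#' perturb the global stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
stopIfMissingColumns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
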