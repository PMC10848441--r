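# Published summary tables from the long-term camera-trap monitoring
# programme in Peneda-Geres National Park (NW Portugal) that this package's
# analyses target. Used as worked-arithmetic inputs in examples and
# self-checks; the underlying images/records live on GBIF and are not
# shipped.

#' Per-year survey summary of the Peneda-Geres monitoring programme
#'
#' Cameras deployed, trap-days of effort, pictures, total sequences and
#' sequences with a species observation, for each survey season 2015 to
#' 2020/21.
#'
#' @return data.frame with columns `year`, `cameras`, `trapDays`,
#'   `pictures`, `sequencesTotal`, `sequencesObservation`.
#' @export
penedaSurveySummary <- function() {
  data.frame(
    year = c("2015", "2016", "2017", "2018", "2019", "2020/21"),
    cameras = c(58L, 61L, 54L, 58L, 57L, 48L),
    trapDays = c(4236, 6744, 7169, 6649, 6830, 9606),
    pictures = c(295562L, 280239L, 52542L, 31437L, 175443L, 99587L),
    sequencesTotal = c(16928L, 18129L, 4608L, 11238L, 12364L, 16924L),
    sequencesObservation = c(2850L, 3761L, 1715L, 1283L, 2902L, 1931L),
    stringsAsFactors = FALSE)
}

#' Per-species yearly sequence counts, Peneda-Geres programme
#'
#' Number of occurrence sequences per species and survey year.
#'
#' @return data.frame: `species`, `scientificName`, `group`
#'   (wild/domestic/other), one column per year, and `total`.
#' @export
penedaSpeciesCounts <- function() {
  df <- data.frame(
    species = c("European roe deer", "Wild boar", "Red fox", "Gray wolf",
                "Stone marten", "Iberian ibex", "Common genet", "Red deer",
                "Eurasian badger", "European rabbit", "Domestic cattle",
                "Domestic horse", "Domestic dog", "Domestic sheep",
                "Domestic goat", "Domestic cat", "Birds", "Rodents",
                "Lizards"),
    scientificName = c("Capreolus capreolus", "Sus scrofa", "Vulpes vulpes",
                       "Canis lupus", "Martes foina", "Capra pyrenaica",
                       "Genetta genetta", "Cervus elaphus", "Meles meles",
                       "Oryctolagus cuniculus", "Bos taurus",
                       "Equus caballus", "Canis lupus familiaris",
                       "Ovis aries", "Capra hircus", "Felis catus", "Aves",
                       "Rodentia", "Reptilia"),
    group = c(rep("wild", 10), rep("domestic", 6), rep("other", 3)),
    y2015 = c(463L, 267L, 92L, 14L, 4L, 0L, 0L, 0L, 1L, 2L, 1297L, 660L,
              38L, 3L, 1L, 0L, 8L, 0L, 0L),
    y2016 = c(520L, 286L, 100L, 40L, 5L, 3L, 2L, 0L, 0L, 6L, 1369L, 1320L,
              68L, 18L, 5L, 0L, 13L, 5L, 1L),
    y2017 = c(150L, 138L, 1L, 5L, 0L, 0L, 0L, 0L, 0L, 0L, 327L, 1088L, 1L,
              4L, 1L, 0L, 0L, 0L, 0L),
    y2018 = c(156L, 169L, 5L, 19L, 1L, 2L, 0L, 5L, 0L, 0L, 460L, 452L, 2L,
              1L, 7L, 1L, 3L, 0L, 0L),
    y2019 = c(616L, 677L, 106L, 37L, 6L, 9L, 5L, 4L, 3L, 0L, 764L, 617L,
              14L, 0L, 9L, 1L, 8L, 25L, 1L),
    y2020_21 = c(643L, 354L, 72L, 5L, 0L, 38L, 3L, 0L, 5L, 0L, 355L, 417L,
                 21L, 0L, 0L, 4L, 11L, 3L, 0L),
    stringsAsFactors = FALSE)
  df$total <- df$y2015 + df$y2016 + df$y2017 + df$y2018 + df$y2019 +
    df$y2020_21
  df
}

#' Density-report components for the six most common species (2019)
#'
#' Point estimates and component coefficients of variation from the
#' programme's 2019 CTDS density analysis: sample size `n` (first-trigger
#' images), `nModel` (after truncation), encounter rate `epsilon`, activity
#' level `a`, detection probability `p` and density `D` (individuals/km^2),
#' each with its printed CV in percent. The density CV is the delta-method
#' composition of the three component CVs (see [deltaCV()]).
#'
#' @return data.frame, one row per species.
#' @export
penedaDensityComponents <- function() {
  data.frame(
    species = c("Gray wolf", "Red fox", "European roe deer", "Wild boar",
                "Domestic horse", "Domestic cattle"),
    scientificName = c("Canis lupus", "Vulpes vulpes", "Capreolus capreolus",
                       "Sus scrofa", "Equus caballus", "Bos taurus"),
    n = c(88L, 146L, 1109L, 2057L, 6801L, 6321L),
    nModel = c(77L, 114L, 672L, 1754L, 2610L, 1046L),
    epsilon = c(0.22, 0.16, 0.83, 1.01, 6.19, 5.19),
    cvEpsilonPct = c(34, 19, 16, 21, 25, 28),
    a = c(0.35, 0.53, 0.44, 0.44, 0.55, 0.36),
    cvAPct = c(9, 11, 4, 3, 2, 2),
    p = c(0.24, 0.16, 0.06, 0.25, 0.11, 0.13),
    cvPPct = c(44, 23, 8, 5, 3, 7),
    D = c(0.15, 0.30, 5.88, 2.59, 10.89, 23.39),
    cvDPct = c(56, 32, 18, 22, 25, 29),
    stringsAsFactors = FALSE)
}
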