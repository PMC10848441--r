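test_that("Camtrap DP tables round-trip through write/read identically", {
  fx <- makeCamtrapFixture()
  dir <- withr::local_tempdir()
  writeCamtrapDP(fx$deployments, fx$occurrences, dir)
  back <- readCamtrapDP(file.path(dir, "deployments.csv"),
                        file.path(dir, "observations.csv"))
  for (col in names(fx$deployments))
    expect_equal(back$deployments[[col]], fx$deployments[[col]], label = col)
  for (col in names(fx$occurrences))
    expect_equal(back$occurrences[[col]], fx$occurrences[[col]], label = col)
  expect_equal(nrow(back$deployments), 3L)
  expect_equal(nrow(back$occurrences), 5L)

  # writing the re-read model reproduces the files byte-identically
  dir2 <- withr::local_tempdir()
  writeCamtrapDP(back$deployments, back$occurrences, dir2)
  expect_identical(readLines(file.path(dir2, "deployments.csv")),
                   readLines(file.path(dir, "deployments.csv")))
  expect_identical(readLines(file.path(dir2, "observations.csv")),
                   readLines(file.path(dir, "observations.csv")))
})

test_that("empty dataset writes header-only files that read back", {
  fx <- makeCamtrapFixture()
  dir <- withr::local_tempdir()
  writeCamtrapDP(fx$deployments[0, ], fx$occurrences[0, ], dir)
  expect_length(readLines(file.path(dir, "observations.csv")), 1L)
  back <- readCamtrapDP(file.path(dir, "deployments.csv"),
                        file.path(dir, "observations.csv"))
  expect_equal(nrow(back$occurrences), 0L)
})

test_that("observationType drives the taxon sentinel mapping", {
  fx <- makeCamtrapFixture()
  dir <- withr::local_tempdir()
  writeCamtrapDP(fx$deployments, fx$occurrences, dir)
  back <- readCamtrapDP(file.path(dir, "deployments.csv"),
                        file.path(dir, "observations.csv"))
  expect_equal(back$occurrences$taxon[4], "blank")
  expect_equal(back$occurrences$taxon[5], "unknown")
  tally <- speciesTally(back$occurrences)
  expect_false(any(c("blank", "unknown") %in% tally$species))
  expect_equal(sum(tally$total), 3L)   # sequences with an observation
  expect_equal(as.integer(attr(tally, "sentinels")), c(1L, 1L))
})

test_that("schema, referential-integrity and timestamp errors are specific", {
  fx <- makeCamtrapFixture()
  dir <- withr::local_tempdir()
  writeCamtrapDP(fx$deployments, fx$occurrences, dir)

  dep <- utils::read.csv(file.path(dir, "deployments.csv"))
  utils::write.csv(dep[, setdiff(names(dep), "deploymentID")],
                   file.path(dir, "dep_bad.csv"), row.names = FALSE)
  expect_error(readCamtrapDP(file.path(dir, "dep_bad.csv"),
                             file.path(dir, "observations.csv")),
               "deploymentID")

  obs <- utils::read.csv(file.path(dir, "observations.csv"))
  obs$deploymentID[2] <- "nonexistent"
  utils::write.csv(obs, file.path(dir, "obs_ref.csv"), row.names = FALSE)
  expect_error(readCamtrapDP(file.path(dir, "deployments.csv"),
                             file.path(dir, "obs_ref.csv")),
               "unknown deploymentID.*nonexistent")

  obs <- utils::read.csv(file.path(dir, "observations.csv"))
  obs$timestamp[3] <- "not-a-time"
  utils::write.csv(obs, file.path(dir, "obs_ts.csv"), row.names = FALSE)
  expect_error(readCamtrapDP(file.path(dir, "deployments.csv"),
                             file.path(dir, "obs_ts.csv")),
               "timestamp at row\\(s\\): 3")
})

test_that("Darwin Core Archive event/occurrence pair maps to the same model", {
  dir <- withr::local_tempdir()
  ev <- data.frame(
    eventID = c("e1", "e2"),
    decimalLatitude = c(42.001, 42.005),
    decimalLongitude = c(-8.2, -8.21),
    eventDate = c("2019-05-07T08:00:00Z/2019-10-08T08:00:00Z",
                  "2019-05-08T08:00:00Z/2019-10-09T08:00:00Z"),
    sampleSizeValue = c(154, 154))
  oc <- data.frame(
    occurrenceID = paste0("o", 1:4),
    eventID = c("e1", "e1", "e2", "e2"),
    scientificName = c("Capreolus capreolus", "Sus scrofa",
                       "Capreolus capreolus", "Vulpes vulpes"),
    occurrenceStatus = "present",
    eventDate = c("2019-05-10", "2019-06-01", "2019-05-12", "2019-07-04"),
    eventTime = c("21:15:00Z", "04:30:00Z", "23:00:00Z", "02:10:00Z"))
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(oc, file.path(dir, "occurrences.csv"), row.names = FALSE)

  x <- readDwcArchive(file.path(dir, "events.csv"),
                      file.path(dir, "occurrences.csv"))
  expect_equal(nrow(x$deployments), 2L)
  expect_equal(nrow(x$occurrences), 4L)
  expect_equal(x$occurrences$taxon[4], "Vulpes vulpes")
  expect_equal(x$occurrences$timestamp[1],
               utcTime("2019-05-10T21:15:00Z"))
  expect_equal(as.numeric(difftime(x$deployments$end[1],
                                   x$deployments$start[1], units = "days")),
               154)

  # interval with end before start is a row-level error
  ev2 <- ev
  ev2$eventDate[2] <- "2019-10-09T08:00:00Z/2019-05-08T08:00:00Z"
  utils::write.csv(ev2, file.path(dir, "events_bad.csv"), row.names = FALSE)
  expect_error(readDwcArchive(file.path(dir, "events_bad.csv"),
                              file.path(dir, "occurrences.csv")),
               "end before start at row\\(s\\): 2")

  # open-ended interval rejected
  ev3 <- ev
  ev3$eventDate[1] <- "2019-05-07T08:00:00Z/"
  utils::write.csv(ev3, file.path(dir, "events_open.csv"), row.names = FALSE)
  expect_error(readDwcArchive(file.path(dir, "events_open.csv"),
                              file.path(dir, "occurrences.csv")),
               "closed 'start/end'")

  # stated effort off by more than half a day: warn, recompute
  ev4 <- ev
  ev4$sampleSizeValue[1] <- 120
  utils::write.csv(ev4, file.path(dir, "events_eff.csv"), row.names = FALSE)
  expect_warning(y <- readDwcArchive(file.path(dir, "events_eff.csv"),
                                     file.path(dir, "occurrences.csv")),
                 "sampleSizeValue")
  eff <- effortSummary(y$deployments)
  expect_equal(unname(effortPerDeployment(eff)[1]), 154)
})

test_that("sequence grouping follows the gap rule and matches brute force", {
  base <- utcTime("2019-05-10T12:00:00Z")
  media <- data.frame(mediaID = paste0("m", 1:5), deploymentID = "d1",
                      timestamp = base + c(0, 1, 2, 500, 501))
  seqs <- groupIntoSequences(media, gapSeconds = 120)
  expect_equal(nrow(seqs), 2L)
  expect_equal(seqs$nImages, c(3L, 2L))
  expect_equal(seqs$timestamp, base + c(0, 500))

  # all images farther apart than the gap: one sequence per image
  far <- data.frame(mediaID = paste0("m", 1:4), deploymentID = "d1",
                    timestamp = base + c(0, 300, 700, 1200))
  expect_equal(groupIntoSequences(far, 120)$nImages, rep(1L, 4))

  # empty input is fine
  expect_equal(nrow(groupIntoSequences(media[0, ], 120)), 0L)

  # random fixture vs the O(n^2) chaining oracle
  withr::with_seed(1, {
    media <- data.frame(
      mediaID = paste0("m", 1:200),
      deploymentID = sample(c("dA", "dB", "dC"), 200, replace = TRUE),
      timestamp = base + round(stats::runif(200, 0, 20000)))
  })
  seqs <- groupIntoSequences(media, 120)
  expect_equal(sort(seqs$nImages), sort(bruteGroupSizes(media, 120)))
  expect_equal(sum(seqs$nImages), 200L)   # exhaustive partition

  # invariance to input order and to timestamp translation
  shuffled <- media[sample(nrow(media)), ]
  expect_equal(groupIntoSequences(shuffled, 120)$nImages, seqs$nImages)
  shifted <- media
  shifted$timestamp <- shifted$timestamp + 86400 * 400
  expect_equal(groupIntoSequences(shifted, 120)$nImages, seqs$nImages)
})

test_that("effort totals are additive and translation-invariant", {
  fx <- makeCamtrapFixture()
  dep <- fx$deployments[1, ]
  dep$end <- dep$start + 10 * 86400
  eff <- effortSummary(dep)
  expect_equal(totalEffort(eff), 10)

  withr::with_seed(7, {
    durations <- stats::runif(20, 30, 160)
  })
  dep <- data.frame(
    deploymentID = sprintf("d%02d", 1:20),
    locationID = sprintf("L%02d", 1:20),
    latitude = 42, longitude = -8.2,
    start = utcTime("2019-05-07T00:00:00Z"),
    end = utcTime("2019-05-07T00:00:00Z") + durations * 86400,
    sensitivity = "high", cameraAngle = 0.73)
  eff <- effortSummary(dep)
  expect_equal(totalEffort(eff), sum(durations))
  expect_equal(sum(effortPerYear(eff)), totalEffort(eff))
  expect_equal(sum(effortPerDeployment(eff)), totalEffort(eff))

  shifted <- dep
  shifted$start <- shifted$start + 86400 * 3
  shifted$end <- shifted$end + 86400 * 3
  expect_equal(totalEffort(effortSummary(shifted)), totalEffort(eff))
})

test_that("species tallies split by year and respect bookkeeping", {
  fx <- makeCamtrapFixture()
  tally <- speciesTally(fx$occurrences)
  roe <- tally[tally$species == "Capreolus capreolus", ]
  expect_equal(roe$total, 2L)
  expect_equal(roe[["2019"]], 2L)
  expect_equal(sum(tally$total), 3L)

  empty <- speciesTally(fx$occurrences[0, ])
  expect_equal(nrow(empty), 0L)
})
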