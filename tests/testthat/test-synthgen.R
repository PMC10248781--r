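test_that("cohort specification validates its fields", {
  expect_error(cohortSpec(nCase = 0), "nCase")
  expect_error(cohortSpec(nCase = 4, nResponder = 5), "nResponder")
  expect_error(cohortSpec(dispersions = c(screen_min = -1)), "dispersions")
  expect_error(cohortSpec(effectMap = c(n_people_called = 1)),
               "n_people_called")
  expect_s4_class(tinySpec(), "CohortSpec")
})

test_that("generation is deterministic given the spec seed", {
  a <- generateCohort(tinySpec(seed = 5))
  b <- generateCohort(tinySpec(seed = 5))
  c <- generateCohort(tinySpec(seed = 6))
  expect_identical(sensorLogs(a)[[1]]@gpsFixes, sensorLogs(b)[[1]]@gpsFixes)
  expect_identical(sensorLogs(a)[[3]]@callLog, sensorLogs(b)[[3]]@callLog)
  expect_identical(gyroBursts(sensorLogs(a)[[2]])[[1]],
                   gyroBursts(sensorLogs(b)[[2]])[[1]])
  expect_identical(weeklyScores(clinicalRecords(a)[[1]]),
                   weeklyScores(clinicalRecords(b)[[1]]))
  expect_false(identical(sensorLogs(a)[[1]]@gpsFixes,
                         sensorLogs(c)[[1]]@gpsFixes))
})

test_that("the default design yields 34 logs with exactly 10 responders", {
  co <- generateCohort(cohortSpec(seed = 2))
  expect_length(sensorLogs(co), 34)
  resp <- vapply(clinicalRecords(co), isResponder, NA)
  expect_identical(sum(resp, na.rm = TRUE), 10L)
  expect_identical(sum(is.na(resp)), 10L)  # controls carry no label
  grp <- vapply(clinicalRecords(co), groupLabel, "")
  expect_identical(unname(table(grp)["case"]), 24L)
})

test_that("responder trajectories honour the 40% CDRS-R decrease rule", {
  for (s in 1:20) {
    rec <- generateClinicalTrajectory(list(group = "case"), responder = TRUE,
                                      seed = s)
    ws <- weeklyScores(rec)
    b <- ws$cdrsr[ws$week == 0]; w8 <- ws$cdrsr[ws$week == 8]
    expect_gte(b, 40)                      # case inclusion threshold
    expect_lte(w8, 0.6 * b)
    non <- generateClinicalTrajectory(list(group = "case"),
                                      responder = FALSE, seed = s + 100)
    wn <- weeklyScores(non)
    expect_gt(wn$cdrsr[wn$week == 8], 0.6 * wn$cdrsr[wn$week == 0])
  }
  ctl <- generateClinicalTrajectory(list(group = "control"), responder = NA,
                                    seed = 1)
  expect_true(is.na(isResponder(ctl)))
  expect_error(generateClinicalTrajectory(list(group = "control"),
                                          responder = TRUE, seed = 1),
               "case subjects")
})

test_that("null effects leave case and control feature means comparable", {
  co <- generateCohort(cohortSpec(effectMap = numeric(), seed = 8))
  pe <- buildPhenotypeExperiment(co)
  cd <- SummarizedExperiment::colData(pe)
  raw <- SummarizedExperiment::assay(pe, "raw")
  for (f in c("screen_usage_duration", "n_calls_received",
              "movement_distance", "momentum")) {
    subjMean <- tapply(raw[f, ], cd$subjectId, mean)
    grp <- tapply(as.character(cd$group), cd$subjectId, `[`, 1)
    tt <- tTestTwoSided(subjMean[grp == "case"], subjMean[grp == "control"])
    expect_lt(abs(tt$t), 4)  # no systematic separation
  }
})

test_that("planted standardized effects are realized at the subject level", {
  # high-replication check on the directly dialled screen-time feature
  d <- 1.5
  co <- generateCohort(cohortSpec(nCase = 30, nControl = 30, nResponder = 1,
                                  daysMonitoring = 7,
                                  effectMap = c(screen_usage_duration = d),
                                  seed = 13))
  pe <- buildPhenotypeExperiment(co)
  cd <- SummarizedExperiment::colData(pe)
  raw <- SummarizedExperiment::assay(pe, "raw")
  subjMean <- tapply(raw["screen_usage_duration", ], cd$subjectId, mean)
  grp <- tapply(as.character(cd$group), cd$subjectId, `[`, 1)
  diff <- mean(subjMean[grp == "case"]) - mean(subjMean[grp == "control"])
  sdPlant <- 60                                 # dial dispersion
  se <- sdPlant * sqrt(1 / 30 + 1 / 30)
  expect_lt(abs(diff - d * sdPlant), 3 * se)
})

test_that("daily call counts follow the configured rate", {
  # ~500 subject-days at a fixed received-call rate of 4/day
  co <- generateCohort(cohortSpec(nCase = 6, nControl = 6, nResponder = 1,
                                  daysMonitoring = 42,
                                  effectMap = numeric(),
                                  baseRates = c(calls_received = 4),
                                  dispersions = c(calls_received = 1e-3),
                                  seed = 21))
  daily <- do.call(rbind, lapply(sensorLogs(co), extractDailyFeatures))
  m <- mean(daily$n_calls_received)
  se <- sqrt(4 / nrow(daily))
  expect_lt(abs(m - 4), 3 * se)
})

test_that("GPS tracks have the 15-minute cadence and planted daily distance", {
  prof <- list(homeLat = 37.5, homeLon = 127, dailyKm = 5)
  trk <- generateGpsTrack(prof, day = 0, seed = 3)
  expect_identical(nrow(trk), 96L)
  expect_equal(unique(diff(as.numeric(trk$timestamp))), 900)
  still <- generateGpsTrack(list(homeLat = 37.5, homeLon = 127, dailyKm = 0),
                            day = 1, seed = 3)
  expect_identical(nrow(unique(still[, c("lat", "lon")])), 1L)
  dists <- vapply(1:300, function(s)
    movementDistance(generateGpsTrack(prof, day = 0, seed = s)), 0)
  expect_lt(abs(mean(dists) - 5), 3 * sd(dists) / sqrt(length(dists)))
})

test_that("gyro bursts have 50 samples and momentum scales with intensity", {
  b <- generateGyroBursts(list(sigma = 0.5), day = 0, seed = 9)
  expect_identical(dim(b), c(96L, 50L, 3L))
  expect_identical(attr(b, "spacing"), 0.1)
  flat <- generateGyroBursts(list(sigma = 0), day = 0, seed = 9)
  expect_equal(max(abs(phenofuzz:::momentumBatch(flat))), 0)
  mom <- function(sig, seeds) mean(vapply(seeds, function(s)
    mean(phenofuzz:::momentumBatch(
      generateGyroBursts(list(sigma = sig), 0, s))), 0))
  m1 <- mom(0.1, 1:30); m5 <- mom(0.5, 1:30)
  expect_lt(abs(m5 / m1 - 5), 0.1)  # momentum proportional to sigma
})

test_that("written cohorts round-trip through JSONL and the manifest", {
  dir <- withr::local_tempdir()
  co <- tinyCohort()
  writeCohort(co, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 7L)
  expect_identical(sum(man$responder, na.rm = TRUE), 2L)
  id <- man$subject_id[1]
  gps <- readLines(file.path(dir, paste0(id, "_gps.jsonl")))
  rec <- jsonlite::fromJSON(gps[1])
  expect_equal(rec$lat, sensorLogs(co)[[1]]@gpsFixes$lat[1])
  first <- jsonlite::fromJSON(
    readLines(file.path(dir, paste0(id, "_gyro.jsonl")), n = 1))
  expect_length(first$x, 50)
})
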