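test_that("movement distance matches the haversine closed form", {
  expect_equal(movementDistance(data.frame(lat = c(0, 0), lon = c(0, 1))),
               6371 * pi / 180, tolerance = 1e-9)
  expect_equal(movementDistance(data.frame(lat = c(0, 0), lon = c(0, 1))),
               111.195, tolerance = 1e-5)
  same <- data.frame(lat = rep(37.5, 96), lon = rep(127, 96))
  expect_identical(movementDistance(same), 0)
  expect_identical(movementDistance(same[1, , drop = FALSE]), 0)
  expect_error(movementDistance(data.frame(lat = c(0, 95), lon = c(0, 0))),
               "latitude")
})

test_that("path length dominates the direct great-circle distance", {
  set.seed(4)
  for (i in 1:20) {
    fixes <- data.frame(lat = 37.5 + cumsum(rnorm(10, 0, 0.01)),
                        lon = 127 + cumsum(rnorm(10, 0, 0.01)))
    direct <- movementDistance(fixes[c(1, 10), ])
    expect_gte(movementDistance(fixes) + 1e-9, direct)
  }
})

test_that("momentum is the trimmed mean of consecutive-difference norms", {
  expect_identical(momentum(matrix(0, 50, 3)), 0)
  expect_equal(momentum(cbind(0.1 * (1:50), 0, 0)), 0.1, tolerance = 1e-12)
  set.seed(7)
  b <- matrix(rnorm(150), 50, 3)
  expect_equal(momentum(b), momentum(b[, c(3, 1, 2)]))   # axis symmetry
  d <- diff(b); mag <- sqrt(rowSums(d^2))
  expect_equal(momentum(b), mean(sort(mag)[2:48]), tolerance = 1e-12)
  expect_error(momentum(matrix(0, 49, 3)), "50")
  arr <- array(rnorm(3 * 50 * 3), c(3, 50, 3))
  expect_equal(phenofuzz:::momentumBatch(arr),
               vapply(1:3, function(i) momentum(arr[i, , ]), 0))
})

test_that("daily call features count and sum by direction", {
  calls <- data.frame(direction = c("in", "in", "out"),
                      duration_s = c(60, 30, 10),
                      contact_id = c("A", "B", "A"))
  got <- dailyCallFeatures(calls)
  expect_equal(got, c(n_calls_sent = 1, n_calls_received = 2,
                      total_time_calls_made = 10,
                      total_time_calls_received = 90, n_people_called = 2))
  # additivity under duplication; distinct contacts unchanged
  twice <- dailyCallFeatures(rbind(calls, calls))
  expect_equal(twice[1:4], 2 * got[1:4])
  expect_equal(twice[["n_people_called"]], 2)
  # order-insensitive
  expect_equal(dailyCallFeatures(calls[c(3, 1, 2), ]), got)
  empty <- dailyCallFeatures(calls[0, ])
  expect_true(all(empty == 0))
  expect_error(dailyCallFeatures(transform(calls, duration_s = -1)), ">= 0")
})

test_that("daily message features mirror the call logic with lengths", {
  msgs <- data.frame(direction = rep("in", 3), char_length = c(10, 20, 30),
                     contact_id = c("A", "A", "B"))
  expect_equal(dailyMessageFeatures(msgs),
               c(n_messages_sent = 0, n_messages_received = 3,
                 total_length_messages_sent = 0,
                 total_length_messages_received = 60, n_people_messaged = 2))
  expect_true(all(dailyMessageFeatures(msgs[0, ]) == 0))
})

test_that("screen usage sums session minutes within one day", {
  day <- as.POSIXct("2020-01-06", tz = "UTC")
  ses <- data.frame(on = day + c(9, 20) * 3600,
                    off = day + c(9.5 * 3600, 20.25 * 3600))
  expect_equal(screenUsage(ses), 45)
  expect_equal(screenUsage(ses[0, ]), 0)
  full <- data.frame(on = day, off = day + 86400)
  expect_equal(screenUsage(full), 1440)
  expect_error(screenUsage(data.frame(on = day + 10, off = day)), "off >= on")
  overlap <- data.frame(on = day + c(0, 1800), off = day + c(3600, 5400))
  expect_error(screenUsage(overlap), "overlap")
})

test_that("week-level representations behave as absolute deviation and SD", {
  fn <- baseFeatureNames()
  daily <- data.frame(subjectId = "S1", date = as.Date("2020-01-06") + 0:6,
                      day = 0:6,
                      matrix(5, 7, 14, dimnames = list(NULL, fn)),
                      check.names = FALSE)
  daily$screen_usage_duration <- 1:7
  pe <- addFeatureClasses(daily)
  dev <- SummarizedExperiment::assay(pe, "deviation")
  wsd <- SummarizedExperiment::assay(pe, "weeklySD")
  # constant feature: both derived representations vanish
  expect_true(all(dev["momentum", ] == 0) && all(wsd["momentum", ] == 0))
  # 1..7: day-1 deviation |1-4| = 3; population SD = 2
  expect_equal(unname(dev["screen_usage_duration", 1]), 3)
  expect_equal(unname(wsd["screen_usage_duration", ]), rep(2, 7))
  # signed deviations sum to zero within the week
  raw <- SummarizedExperiment::assay(pe, "raw")
  expect_equal(sum(raw["screen_usage_duration", ] - 4), 0)
  # sample-SD convention stays available
  peS <- addFeatureClasses(daily, sdType = "sample")
  expect_equal(unname(SummarizedExperiment::assay(peS, "weeklySD")[
    "screen_usage_duration", 1]), sd(1:7))
})

test_that("weekly SD is constant within each subject-week", {
  co <- tinyCohort()
  pe <- buildPhenotypeExperiment(co)
  cd <- SummarizedExperiment::colData(pe)
  wsd <- SummarizedExperiment::assay(pe, "weeklySD")
  grp <- paste(cd$subjectId, cd$week)
  for (f in c("screen_usage_duration", "n_messages_sent"))
    expect_true(all(tapply(wsd[f, ], grp,
                           function(v) diff(range(v))) == 0))
})

test_that("task datasets carry the documented shape and exclusions", {
  co <- tinyCohort()
  pe <- buildPhenotypeExperiment(co)
  diag <- buildDataset(pe, "diagnosis")
  expect_identical(ncol(diag@x), 42L)
  expect_lte(nrow(diag@x), 7 * 7)          # subjects x baseline days
  expect_identical(levels(diag@y), c("case", "control"))
  resp <- buildDataset(pe, "response")
  expect_identical(ncol(resp@x), 44L)
  expect_true(all(c("dose_mg", "max_dose_mg") %in% colnames(resp@x)))
  # controls never enter the response task
  ctl <- vapply(clinicalRecords(co),
                function(r) if (groupLabel(r) == "control") subjectId(r)
                else NA_character_, "")
  expect_false(any(resp@subject %in% stats::na.omit(ctl)))
  expect_error(buildDataset(pe, "nonsense"))
  # all extracted features are non-negative
  expect_true(all(diag@x >= 0))
})

test_that("extraction recovers the planted screen-time mean (round trip)", {
  co <- generateCohort(cohortSpec(nCase = 2, nControl = 2, nResponder = 1,
                                  daysMonitoring = 28,
                                  effectMap = numeric(),
                                  dispersions = c(screen_min = 1e-3),
                                  seed = 31))
  daily <- do.call(rbind, lapply(sensorLogs(co), extractDailyFeatures))
  m <- mean(daily$screen_usage_duration)
  se <- sd(daily$screen_usage_duration) / sqrt(nrow(daily))
  expect_lt(abs(m - 240), 3 * se + 5)
})
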