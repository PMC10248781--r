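# Synthetic cohort generator: raw smartphone event streams plus clinical
# trajectories with controllable, subject-level planted group effects.

.defaultBaseRates <- c(
  screen_min = 240, distance_km = 5, gyro_sd = 0.5,
  calls_received = 3, calls_sent = 2,
  messages_received = 10, messages_sent = 8, images = 2,
  call_time_made_s = 240, call_time_received_s = 360,
  msg_len_received = 400, msg_len_sent = 320)

.defaultDispersions <- c(
  screen_min = 60, distance_km = 1.5, gyro_sd = 0.12,
  calls_received = 1, calls_sent = 0.8,
  messages_received = 3, messages_sent = 2.5, images = 0.7,
  call_time_made_s = 80, call_time_received_s = 120,
  msg_len_received = 120, msg_len_sent = 100)

# Baseline characteristics by group used for clinical trajectories
# (means and SDs of the clinician-rated scales).
.clinNorms <- list(
  case = list(cdrsr = c(62.4, 7.0), cdi = c(37.0, 6.9), cssrs = c(3.6, 1.5),
              scared = c(45.0, 17.6), iq = c(104.9, 16.6),
              faces = c(41.8, 12.5), age = c(15.4, 1.4), pFemale = 17 / 24,
              cgis = c(4.6, 0.6), cgas = c(52, 7)),
  control = list(cdrsr = c(27.4, 9.1), cdi = c(6.8, 7.3), cssrs = c(0.3, 0.9),
                 scared = c(12.7, 12.4), iq = c(111.6, 6.1),
                 faces = c(59.6, 12.7), age = c(13.7, 0.7), pFemale = 0.5,
                 cgis = c(1.2, 0.4), cgas = c(85, 5)))

#' Construct a synthetic cohort specification
#'
#' @param nCase,nControl,nResponder group sizes. Defaults mirror the study
#'   design: 24 adolescents with MDD of whom 10 respond to treatment, and
#'   10 healthy controls.
#' @param daysBaseline days of pre-treatment monitoring (default 7).
#' @param daysMonitoring total monitored days (default 35, i.e. 5 weeks).
#' @param effectMap named numeric vector of standardized case-vs-control
#'   effects; names are base feature names (see [baseFeatureNames()]).
#'   An effect of `d` shifts the case-group mean of the feature's generator
#'   dial by `d` between-subject SDs. The default plants the group
#'   differences reported for this design: more screen time, more received
#'   calls and longer movement distances in the case group.
#' @param responderEffectMap like `effectMap` but responder vs nonresponder
#'   within cases; empty by default (no prominent responder differences).
#' @param baseRates,dispersions daily means and between-subject SDs of the
#'   generator dials; partial named vectors override the defaults.
#' @param contactPool per-subject contact pool size (Zipf-weighted draws).
#' @param seed master integer seed; every stream derives its own sub-seed.
#'
#' @return A validated [CohortSpec-class] object.
#' @export
#' @examples
#' cohortSpec(nCase = 4, nControl = 3, nResponder = 2, seed = 1)
cohortSpec <- function(nCase = 24, nControl = 10, nResponder = 10,
                       daysBaseline = 7, daysMonitoring = 35,
                       effectMap = c(screen_usage_duration = 0.8,
                                     n_calls_received = 0.6,
                                     movement_distance = 0.6),
                       responderEffectMap = numeric(),
                       baseRates = numeric(), dispersions = numeric(),
                       contactPool = 15, seed = 1) {
  br <- .defaultBaseRates; br[names(baseRates)] <- baseRates
  dp <- .defaultDispersions; dp[names(dispersions)] <- dispersions
  new("CohortSpec", nCase = as.integer(nCase),
      nControl = as.integer(nControl), nResponder = as.integer(nResponder),
      daysBaseline = as.integer(daysBaseline),
      daysMonitoring = as.integer(daysMonitoring),
      effectMap = effectMap, responderEffectMap = responderEffectMap,
      baseRates = br, dispersions = dp,
      contactPool = as.integer(contactPool), seed = as.integer(seed))
}

.studyEpoch <- function() as.Date("2020-01-06")

# UTC timestamps for second-offsets within one monitored day; numeric
# construction keeps this cheap inside per-day generation loops
.dayTimes <- function(startDate, day, secs) {
  structure(as.numeric(startDate) * 86400 + day * 86400 + secs,
            class = c("POSIXct", "POSIXt"), tzone = "UTC")
}

# data.frame without the validation overhead (columns are known-good)
.fastDf <- function(...) {
  l <- list(...)
  structure(l, class = "data.frame",
            row.names = .set_row_names(length(l[[1]])))
}

# row-bind a list of homogeneous data.frames by concatenating columns
.rbindDf <- function(lst) {
  cols <- names(lst[[1]])
  out <- lapply(cols, function(cn) do.call(c, lapply(lst, `[[`, cn)))
  names(out) <- cols
  .fastDf2(out)
}

.fastDf2 <- function(l) structure(l, class = "data.frame",
                                  row.names = .set_row_names(length(l[[1]])))

#' Generate one day of GPS fixes
#'
#' A home-anchored random walk sampled every 15 minutes: 96 fixes whose
#' expected total path length equals the profile's daily distance. Step
#' lengths are gamma-distributed (shape 2) and headings uniform; positions
#' are laid out on a local tangent plane around the home anchor.
#'
#' @param profile list with `homeLat`, `homeLon` (degrees), `dailyKm`
#'   (expected total path length, km) and optionally `startDate`, `stepShape`.
#' @param day 0-based day index within the monitoring window.
#' @param seed integer seed for this day's track.
#'
#' @return data.frame with 96 rows: `timestamp` (POSIXct UTC), `lat`, `lon`.
#' @export
#' @examples
#' trk <- generateGpsTrack(list(homeLat = 37.5, homeLon = 127, dailyKm = 5),
#'                         day = 0, seed = 1)
#' nrow(trk)  # 96 fixes: one every 15 minutes
generateGpsTrack <- function(profile, day, seed) {
  startDate <- profile$startDate %||% .studyEpoch()
  shape <- profile$stepShape %||% 2
  nFix <- 96L
  ts <- .dayTimes(startDate, day, seq(0, by = 900, length.out = nFix))
  if (is.null(profile$dailyKm) || profile$dailyKm <= 0)
    return(.fastDf(timestamp = ts, lat = rep(profile$homeLat, nFix),
                   lon = rep(profile$homeLon, nFix)))
  withSeed(seed, {
    steps <- rgamma(nFix - 1L, shape = shape,
                    scale = profile$dailyKm / (nFix - 1L) / shape)
    theta <- runif(nFix - 1L, 0, 2 * pi)
    north <- c(0, cumsum(steps * cos(theta)))
    east <- c(0, cumsum(steps * sin(theta)))
    lat <- profile$homeLat + north / .kmPerDegree
    lon <- profile$homeLon +
      east / (.kmPerDegree * cos(profile$homeLat * pi / 180))
    .fastDf(timestamp = ts, lat = lat, lon = lon)
  })
}

#' Generate one day of gyroscope bursts
#'
#' 96 bursts (one every 15 minutes), each 50 triaxial rotation-rate samples
#' at 0.1 s spacing, drawn as white noise with the profile's intensity.
#' Expected burst momentum is proportional to `sigma`.
#'
#' @param profile list with `sigma` (rad/s scale; 0 gives constant bursts)
#'   and optionally `startDate`.
#' @param day 0-based day index.
#' @param seed integer seed.
#'
#' @return A `96 x 50 x 3` array with attributes `timestamps` (burst start
#'   times) and `spacing` (0.1 seconds).
#' @export
generateGyroBursts <- function(profile, day, seed) {
  startDate <- profile$startDate %||% .studyEpoch()
  nBurst <- 96L
  vals <- if (is.null(profile$sigma) || profile$sigma <= 0)
    numeric(nBurst * 50L * 3L)
  else withSeed(seed, rnorm(nBurst * 50L * 3L, 0, profile$sigma))
  # one structure() call: repeated attr<- would copy the array each time
  structure(vals, dim = c(nBurst, 50L, 3L),
            timestamps = .dayTimes(startDate, day,
                                   seq(0, by = 900, length.out = nBurst)),
            spacing = 0.1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one day of call or message events
.generateCommDay <- function(day, startDate, lambdaIn, lambdaOut,
                             meanIn, meanOut, pool, kind) {
  nIn <- rpois(1L, lambdaIn); nOut <- rpois(1L, lambdaOut)
  n <- nIn + nOut
  if (n == 0L)
    return(NULL)
  secs <- sort(runif(n, 0, 86395)) + seq_len(n) * 1e-4
  direction <- sample(c(rep("in", nIn), rep("out", nOut)))
  contact <- sample(seq_along(pool), n, replace = TRUE, prob = pool)
  mu <- ifelse(direction == "in", meanIn, meanOut)
  df <- .fastDf(timestamp = .dayTimes(startDate, day, secs),
               direction = direction)
  if (kind == "call") {
    # log-normal durations with the subject's per-call mean
    df$duration_s <- rlnorm(n, meanlog = log(pmax(mu, 1)) - 0.18, sdlog = 0.6)
  } else {
    # geometric (shifted by 1) character counts with the subject's mean
    df$char_length <- rgeom(n, prob = 1 / pmax(mu, 1.01)) + 1L
  }
  df$contact_id <- sprintf("C%03d", contact)
  df
}

# one day of screen sessions: alternating exponential off/on holding times
# whose stationary on-fraction matches the daily target; clipped to the day
.generateScreenDay <- function(day, startDate, targetMin, meanOn = 10) {
  targetMin <- min(max(targetMin, 1), 1380)
  meanOff <- meanOn * (1440 - targetMin) / targetMin
  # draw enough off/on cycles in one batch to cover the day
  k <- ceiling(3 * 1440 / (meanOn + meanOff)) + 10L
  repeat {
    offs <- rexp(k, 1 / meanOff); ons <- rexp(k, 1 / meanOn)
    ends <- cumsum(offs + ons)
    if (ends[k] >= 1440) break
    k <- k * 2L
  }
  on <- ends - ons; off <- ends
  keep <- on < 1440
  on <- on[keep]; off <- pmin(off[keep], 1440)
  if (!length(on)) return(NULL)
  .fastDf(on = .dayTimes(startDate, day, on * 60),
          off = .dayTimes(startDate, day, off * 60))
}

# escitalopram-style dose schedule: 5 mg first treatment week, 10 mg the
# next, then upward titration to the subject's maximum (10-25 mg)
.generateDoses <- function(nDays, daysBaseline, isCase, seed) {
  dose <- numeric(nDays)
  if (isCase) {
    maxDose <- withSeed(seed,
      sample(c(10, 15, 20, 25), 1L, prob = c(0.35, 0.3, 0.2, 0.15)))
    for (d in seq_len(nDays) - 1L) {
      if (d < daysBaseline) next
      wk <- (d - daysBaseline) %/% 7L
      dose[d + 1L] <- min(5 + 5 * wk, maxDose)
    }
  }
  dose
}

.truncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:200) {
    x <- rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Generate a clinical score trajectory for one subject
#'
#' Draws baseline scale scores from the group norms and a weekly CDRS-R
#' trajectory consistent with the responder definition: responders reach a
#' week-8 CDRS-R of at most 60% of baseline (a decrease of at least 40%),
#' nonresponders stay above it. Cases carry weeks 0 through 8; controls the
#' five monitored weeks. Case baselines satisfy the CDRS-R >= 40 inclusion
#' threshold.
#'
#' @param profile list with `group` (`"case"` or `"control"`) and optionally
#'   `subjectId`.
#' @param responder logical; must be `NA` for controls.
#' @param seed integer seed.
#'
#' @return A [ClinicalRecord-class].
#' @export
generateClinicalTrajectory <- function(profile, responder, seed) {
  group <- match.arg(profile$group, c("case", "control"))
  if (group == "control" && isTRUE(responder))
    stop("responder trajectories are defined for case subjects only")
  if (group == "control") responder <- NA
  nm <- .clinNorms[[group]]
  withSeed(seed, {
    baseline <- if (group == "case")
      .truncnorm1(nm$cdrsr[1], nm$cdrsr[2], 40, 113)
    else .truncnorm1(nm$cdrsr[1], nm$cdrsr[2], 17, 113)
    weeks <- if (group == "case") 0:8 else 0:4
    if (group == "case") {
      ratio <- if (isTRUE(responder)) runif(1, 0.35, 0.58)
               else runif(1, 0.65, 0.95)
      traj <- baseline * (1 + (ratio - 1) * weeks / 8) +
        c(0, rnorm(length(weeks) - 1L, 0, 2.5))
      traj <- pmin(pmax(roundHalfUp(traj), 17), 113)
      traj[1] <- roundHalfUp(baseline)
      w8 <- roundHalfUp(baseline * ratio)
      # enforce the 40% decrease rule exactly at week 8
      if (isTRUE(responder) && w8 > 0.6 * traj[1]) w8 <- floor(0.6 * traj[1])
      if (!isTRUE(responder) && (traj[1] - w8) / traj[1] >= 0.4)
        w8 <- floor(0.6 * traj[1]) + 1L
      traj[length(traj)] <- max(w8, 17)
    } else {
      traj <- pmin(pmax(roundHalfUp(
        baseline + c(0, rnorm(length(weeks) - 1L, 0, 2))), 17), 113)
    }
    improve <- if (group == "case") traj / traj[1] else rep(1, length(weeks))
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    cdi0 <- .truncnorm1(nm$cdi[1], nm$cdi[2], 0, 54)
    cssrs0 <- .truncnorm1(nm$cssrs[1], nm$cssrs[2], 0, 10)
    cgis0 <- .truncnorm1(nm$cgis[1], nm$cgis[2], 1, 7)
    cgas0 <- .truncnorm1(nm$cgas[1], nm$cgas[2], 1, 100)
    ws <- data.frame(
      week = weeks,
      cdrsr = traj,
      cdi = clamp(roundHalfUp(cdi0 * improve + rnorm(length(weeks), 0, 1.5)), 0, 54),
      cssrs = clamp(roundHalfUp(cssrs0 * improve + rnorm(length(weeks), 0, 0.4)), 0, 10),
      cgis = clamp(roundHalfUp(cgis0 * improve + rnorm(length(weeks), 0, 0.3)), 1, 7),
      cgas = clamp(roundHalfUp(cgas0 / pmax(improve, 0.3) + rnorm(length(weeks), 0, 2)), 1, 100))
    bs <- list(scared = round(.truncnorm1(nm$scared[1], nm$scared[2], 0, 82), 1),
               iq = roundHalfUp(.truncnorm1(nm$iq[1], nm$iq[2], 70, 145)),
               faces = round(.truncnorm1(nm$faces[1], nm$faces[2], 10, 90), 1),
               age = round(.truncnorm1(nm$age[1], nm$age[2], 12, 18), 1),
               sex = if (runif(1) < nm$pFemale) "female" else "male")
    new("ClinicalRecord",
        subjectId = profile$subjectId %||% "S00", group = group,
        weeklyScores = ws, baselineScores = bs,
        responder = as.logical(responder))
  })
}

# subject-level dial values: base + planted standardized effects + noise
.subjectDials <- function(spec, isCase, isResp, seed) {
  z <- withSeed(seed, rnorm(length(.dialNames)))
  names(z) <- .dialNames
  shift <- setNames(numeric(length(.dialNames)), .dialNames)
  if (isCase && length(spec@effectMap))
    shift[.featureDial[names(spec@effectMap)]] <-
      shift[.featureDial[names(spec@effectMap)]] + spec@effectMap
  if (isTRUE(isResp) && length(spec@responderEffectMap))
    shift[.featureDial[names(spec@responderEffectMap)]] <-
      shift[.featureDial[names(spec@responderEffectMap)]] +
      spec@responderEffectMap
  d <- spec@baseRates + spec@dispersions * (shift + z)
  # keep every dial physically meaningful
  d["screen_min"] <- min(max(d["screen_min"], 5), 1380)
  d["distance_km"] <- max(d["distance_km"], 0)
  d["gyro_sd"] <- max(d["gyro_sd"], 0.005)
  for (r in c("calls_received", "calls_sent", "messages_received",
              "messages_sent", "images"))
    d[r] <- max(d[r], 0.05)
  for (r in c("call_time_made_s", "call_time_received_s"))
    d[r] <- max(d[r], 1)
  for (r in c("msg_len_received", "msg_len_sent"))
    d[r] <- max(d[r], 5)
  d
}

.generateSensorLog <- function(id, spec, dials, seed) {
  nDays <- spec@daysMonitoring
  startDate <- .studyEpoch()
  home <- withSeed(subSeed(seed, 11), c(37.5 + runif(1, -0.1, 0.1),
                                        127.0 + runif(1, -0.1, 0.1)))
  pool <- 1 / seq_len(spec@contactPool)  # Zipf contact weights
  gpsProfile <- list(homeLat = home[1], homeLon = home[2],
                     dailyKm = unname(dials["distance_km"]),
                     startDate = startDate)
  gyroProfile <- list(sigma = unname(dials["gyro_sd"]), startDate = startDate)
  gps <- vector("list", nDays); gyro <- vector("list", nDays)
  calls <- vector("list", nDays); msgs <- vector("list", nDays)
  screen <- vector("list", nDays); img <- integer(nDays)
  # per-call / per-message means chosen so that the subject's expected daily
  # totals equal the total-time / total-length dials independently of counts
  callMeanIn <- dials["call_time_received_s"] / max(dials["calls_received"], 0.2)
  callMeanOut <- dials["call_time_made_s"] / max(dials["calls_sent"], 0.2)
  msgMeanIn <- dials["msg_len_received"] / max(dials["messages_received"], 0.2)
  msgMeanOut <- dials["msg_len_sent"] / max(dials["messages_sent"], 0.2)
  for (d in seq_len(nDays) - 1L) {
    gps[[d + 1L]] <- generateGpsTrack(gpsProfile, d, subSeed(seed, 2, d))
    gyro[[d + 1L]] <- generateGyroBursts(gyroProfile, d, subSeed(seed, 3, d))
    calls[[d + 1L]] <- withSeed(subSeed(seed, 4, d),
      .generateCommDay(d, startDate, dials["calls_received"],
                       dials["calls_sent"], callMeanIn, callMeanOut,
                       pool, "call"))
    msgs[[d + 1L]] <- withSeed(subSeed(seed, 5, d),
      .generateCommDay(d, startDate, dials["messages_received"],
                       dials["messages_sent"], msgMeanIn, msgMeanOut,
                       pool, "message"))
    screen[[d + 1L]] <- withSeed(subSeed(seed, 6, d),
      .generateScreenDay(d, startDate, dials["screen_min"]))
    img[d + 1L] <- withSeed(subSeed(seed, 7, d),
                            rpois(1L, dials["images"]))
  }
  bindRows <- function(lst, template) {
    lst <- lst[!vapply(lst, is.null, TRUE)]
    if (!length(lst)) return(template)
    .rbindDf(lst)
  }
  callTemplate <- data.frame(timestamp = .dayTimes(startDate, 0, numeric(0)),
                             direction = character(0),
                             duration_s = numeric(0),
                             contact_id = character(0))
  msgTemplate <- data.frame(timestamp = .dayTimes(startDate, 0, numeric(0)),
                            direction = character(0),
                            char_length = integer(0),
                            contact_id = character(0))
  scrTemplate <- data.frame(on = .dayTimes(startDate, 0, numeric(0)),
                            off = .dayTimes(startDate, 0, numeric(0)))
  dates <- startDate + seq_len(nDays) - 1L
  new("SensorEventLog", subjectId = id, startDate = startDate,
      nDays = as.integer(nDays),
      gpsFixes = .rbindDf(gps),
      gyroBursts = gyro,
      callLog = bindRows(calls, callTemplate),
      messageLog = bindRows(msgs, msgTemplate),
      screenSessions = bindRows(screen, scrTemplate),
      imageCounts = data.frame(date = dates, count = img),
      doseSchedule = data.frame(
        date = dates,
        dose_mg = .generateDoses(nDays, spec@daysBaseline,
                                 FALSE, subSeed(seed, 8))))
}

#' Generate a synthetic digital-phenotyping cohort
#'
#' Produces one [SensorEventLog-class] and one [ClinicalRecord-class] per
#' subject under the design in `spec`. Generation is fully deterministic
#' given `spec@seed`: every subject and stream derives an independent
#' sub-seed from it. Planted effects are realized at the subject level (see
#' [cohortSpec()]), and exactly `nResponder` case subjects receive
#' responder trajectories satisfying the 40% CDRS-R decrease rule.
#'
#' @param spec a [CohortSpec-class].
#' @return A [DigitalCohort-class] with `nCase + nControl` subjects.
#' @export
#' @examples
#' cohort <- generateCohort(cohortSpec(nCase = 3, nControl = 2,
#'                                     nResponder = 1, daysMonitoring = 7,
#'                                     seed = 7))
#' cohort
generateCohort <- function(spec) {
  validObject(spec)
  n <- spec@nCase + spec@nControl
  ids <- sprintf("S%03d", seq_len(n))
  groups <- rep(c("case", "control"), c(spec@nCase, spec@nControl))
  respIdx <- withSeed(subSeed(spec@seed, 101),
                      sample(spec@nCase, spec@nResponder))
  logs <- vector("list", n); recs <- vector("list", n)
  for (i in seq_len(n)) {
    isCase <- groups[i] == "case"
    isResp <- if (isCase) i %in% respIdx else NA
    subjectSeed <- subSeed(spec@seed, i)
    dials <- .subjectDials(spec, isCase, isResp, subSeed(subjectSeed, 1))
    log <- .generateSensorLog(ids[i], spec, dials, subjectSeed)
    if (isCase)
      log@doseSchedule$dose_mg <- .generateDoses(
        spec@daysMonitoring, spec@daysBaseline, TRUE,
        subSeed(subjectSeed, 8))
    rec <- generateClinicalTrajectory(
      list(group = groups[i], subjectId = ids[i]),
      responder = isResp, seed = subSeed(subjectSeed, 99))
    logs[[i]] <- log; recs[[i]] <- rec
  }
  new("DigitalCohort", sensorLogs = logs, clinicalRecords = recs,
      spec = spec)
}
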