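# Daily feature extraction from raw event streams, and assembly of the
# three per-feature representations (raw, |deviation from week mean|,
# weekly SD) into a PhenotypeExperiment.

#' Total daily movement distance from GPS fixes
#'
#' Sums great-circle (haversine, Earth radius 6371 km) distances between
#' consecutive fixes of one subject-day.
#'
#' @param fixes data.frame with `lat`, `lon` in degrees, time-ordered.
#' @return Distance in km; 0 when fewer than 2 fixes.
#' @export
#' @examples
#' movementDistance(data.frame(lat = c(0, 0), lon = c(0, 1)))  # 111.195 km
movementDistance <- function(fixes) {
  if (nrow(fixes) < 2L) return(0)
  if (any(abs(fixes$lat) > 90) || any(abs(fixes$lon) > 180))
    stop("latitude must lie in [-90, 90] and longitude in [-180, 180]")
  p <- cbind(fixes$lon, fixes$lat)
  n <- nrow(p)
  sum(geosphere::distHaversine(p[-n, , drop = FALSE],
                               p[-1, , drop = FALSE], r = 6371))
}

#' Rotational momentum of one gyroscope burst
#'
#' The magnitude `sqrt(dx^2 + dy^2 + dz^2)` of each of the 49 consecutive
#' sample differences of a 50-sample triaxial burst, averaged after removing
#' the single largest and single smallest magnitude (a trimmed mean over the
#' remaining 47). A constant burst has momentum 0.
#'
#' @param burst numeric `50 x 3` matrix of rotation rates (rad/s).
#' @return Non-negative scalar (rad/s).
#' @export
#' @examples
#' momentum(matrix(0, 50, 3))                      # 0
#' momentum(cbind(0.1 * (1:50), 0, 0))             # 0.1
momentum <- function(burst) {
  burst <- as.matrix(burst)
  if (nrow(burst) != 50L || ncol(burst) != 3L)
    stop("a gyroscope burst must be a 50 x 3 sample matrix")
  d <- diff(burst)
  mag <- sqrt(rowSums(d^2))
  (sum(mag) - max(mag) - min(mag)) / (length(mag) - 2L)
}

# vectorized momentum over an nb x 50 x 3 array of bursts (compiled loop)
momentumBatch <- function(bursts) {
  stopifnot2(length(dim(bursts)) == 3L && dim(bursts)[2] == 50L,
             "bursts must be an nb x 50 x 3 array")
  momentum_batch_cpp(bursts)
}

#' Daily phone-call features
#'
#' @param calls data.frame for one subject-day with `direction`
#'   (`"in"`/`"out"`), `duration_s` and `contact_id`.
#' @return Named numeric vector: `n_calls_sent`, `n_calls_received`,
#'   `total_time_calls_made`, `total_time_calls_received` (seconds) and
#'   `n_people_called` (distinct contacts across both directions).
#' @export
#' @examples
#' dailyCallFeatures(data.frame(direction = c("in", "in", "out"),
#'                              duration_s = c(60, 30, 10),
#'                              contact_id = c("A", "B", "A")))
dailyCallFeatures <- function(calls) {
  if (nrow(calls) && any(calls$duration_s < 0))
    stop("call durations must be >= 0")
  isIn <- calls$direction == "in"
  c(n_calls_sent = sum(!isIn),
    n_calls_received = sum(isIn),
    total_time_calls_made = sum(calls$duration_s[!isIn]),
    total_time_calls_received = sum(calls$duration_s[isIn]),
    n_people_called = length(unique(calls$contact_id)))
}

#' Daily text-message features
#'
#' @param messages data.frame for one subject-day with `direction`,
#'   `char_length` and `contact_id`.
#' @return Named numeric vector: `n_messages_sent`, `n_messages_received`,
#'   `total_length_messages_sent`, `total_length_messages_received`
#'   (characters) and `n_people_messaged`.
#' @export
dailyMessageFeatures <- function(messages) {
  if (nrow(messages) && any(messages$char_length < 0))
    stop("message lengths must be >= 0")
  isIn <- messages$direction == "in"
  c(n_messages_sent = sum(!isIn),
    n_messages_received = sum(isIn),
    total_length_messages_sent = sum(messages$char_length[!isIn]),
    total_length_messages_received = sum(messages$char_length[isIn]),
    n_people_messaged = length(unique(messages$contact_id)))
}

#' Daily screen usage in minutes
#'
#' @param sessions data.frame with `on`, `off` (POSIXct or minutes),
#'   non-overlapping and clipped to one day.
#' @return Total on-time in minutes (at most 1440).
#' @export
screenUsage <- function(sessions) {
  if (!nrow(sessions)) return(0)
  on <- as.numeric(sessions$on); off <- as.numeric(sessions$off)
  if (any(off < on)) stop("screen sessions must have off >= on")
  o <- order(on)
  if (length(on) > 1L && any(on[o][-1] < off[o][-length(off)]))
    stop("screen sessions must not overlap")
  total <- sum(off - on)
  if (inherits(sessions$on, "POSIXt")) total <- total / 60
  min(total, 1440)
}

#' Extract the daily feature vectors of one subject
#'
#' Walks the monitoring window day by day and computes the 14 base features
#' from the raw streams, plus that day's medication dose. Days with an
#' absent stream contribute 0 for the affected features and are flagged in
#' the `complete` column.
#'
#' @param log a [SensorEventLog-class].
#' @return data.frame with one row per monitored day: `subjectId`, `date`,
#'   `day`, the 14 base features, `dose_mg`, `complete`.
#' @export
extractDailyFeatures <- function(log) {
  validObject(log)
  startNum <- as.numeric(as.POSIXct(log@startDate, tz = "UTC"))
  nDays <- log@nDays
  dayOf <- function(ts) floor((as.numeric(ts) - startNum) / 86400)
  gpsDay <- dayOf(log@gpsFixes$timestamp)
  callDay <- dayOf(log@callLog$timestamp)
  msgDay <- dayOf(log@messageLog$timestamp)
  scrDay <- dayOf(log@screenSessions$on)
  feats <- matrix(0, nrow = nDays, ncol = 14,
                  dimnames = list(NULL, baseFeatureNames()))
  complete <- rep(TRUE, nDays)
  # all consecutive-fix distances in one pass, summed within days
  if (nrow(log@gpsFixes) > 1L) {
    p <- cbind(log@gpsFixes$lon, log@gpsFixes$lat)
    n <- nrow(p)
    seg <- geosphere::distHaversine(p[-n, , drop = FALSE],
                                    p[-1, , drop = FALSE], r = 6371)
    sameDay <- gpsDay[-n] == gpsDay[-1]
    dayKm <- tapply(seg[sameDay], gpsDay[-n][sameDay], sum)
    hit <- as.integer(names(dayKm)) + 1L
    feats[hit[hit >= 1 & hit <= nDays], "movement_distance"] <-
      dayKm[hit >= 1 & hit <= nDays]
  }
  complete[!(seq_len(nDays) - 1L) %in% gpsDay] <- FALSE
  callIdx <- split(seq_len(nrow(log@callLog)), factor(callDay, 0:(nDays - 1L)))
  msgIdx <- split(seq_len(nrow(log@messageLog)), factor(msgDay, 0:(nDays - 1L)))
  scrIdx <- split(seq_len(nrow(log@screenSessions)),
                  factor(scrDay, 0:(nDays - 1L)))
  for (d in seq_len(nDays) - 1L) {
    bursts <- if (d + 1L <= length(log@gyroBursts)) log@gyroBursts[[d + 1L]]
              else NULL
    if (!is.null(bursts) && length(bursts)) {
      feats[d + 1L, "momentum"] <- mean(momentumBatch(bursts))
    } else complete[d + 1L] <- FALSE
    cf <- dailyCallFeatures(log@callLog[callIdx[[d + 1L]], , drop = FALSE])
    feats[d + 1L, names(cf)] <- cf
    mf <- dailyMessageFeatures(log@messageLog[msgIdx[[d + 1L]], , drop = FALSE])
    feats[d + 1L, names(mf)] <- mf
    feats[d + 1L, "screen_usage_duration"] <-
      screenUsage(log@screenSessions[scrIdx[[d + 1L]], , drop = FALSE])
  }
  dates <- log@startDate + seq_len(nDays) - 1L
  ic <- log@imageCounts
  feats[, "added_image_files"] <-
    ic$count[match(dates, ic$date)] %|NA|% 0
  dose <- log@doseSchedule$dose_mg[match(dates, log@doseSchedule$date)] %|NA|% 0
  data.frame(subjectId = log@subjectId, date = dates,
             day = seq_len(nDays) - 1L, feats, dose_mg = dose,
             complete = complete, check.names = FALSE)
}

`%|NA|%` <- function(x, repl) { x[is.na(x)] <- repl; x }

#' Attach the three per-feature representations
#'
#' Assigns every subject-day to a subject-anchored study week (7-day blocks
#' from monitoring start) and derives, for every base feature, the absolute
#' deviation from the subject-week mean and the subject-week standard
#' deviation (constant across the week).
#'
#' @param daily data.frame as returned by [extractDailyFeatures()] (rows
#'   from several subjects may be concatenated).
#' @param sdType `"population"` (divide by n; default) or `"sample"`.
#' @return A [PhenotypeExperiment-class] with assays `raw`, `deviation`,
#'   `weeklySD`.
#' @export
addFeatureClasses <- function(daily, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  fn <- baseFeatureNames()
  stopifnot2(all(fn %in% colnames(daily)),
             "'daily' must contain the 14 base feature columns")
  week <- daily$day %/% 7L
  grp <- interaction(daily$subjectId, week, drop = TRUE)
  popSd <- function(v) sqrt(mean((v - mean(v))^2))
  sdFun <- if (sdType == "population") popSd else stats::sd
  raw <- t(as.matrix(daily[, fn]))
  dev <- raw; wsd <- raw
  for (f in fn) {
    x <- daily[[f]]
    m <- stats::ave(x, grp, FUN = mean)
    dev[f, ] <- abs(x - m)
    wsd[f, ] <- stats::ave(x, grp, FUN = sdFun)
  }
  cd <- S4Vectors::DataFrame(subjectId = daily$subjectId, date = daily$date,
                             day = daily$day, week = week)
  if ("dose_mg" %in% colnames(daily)) cd$dose_mg <- daily$dose_mg
  if ("complete" %in% colnames(daily)) cd$complete <- daily$complete
  colnames(raw) <- colnames(dev) <- colnames(wsd) <-
    paste(daily$subjectId, daily$day, sep = ".")
  rownames(cd) <- colnames(raw)
  new("PhenotypeExperiment", SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw, deviation = dev, weeklySD = wsd),
    colData = cd))
}

#' Build the feature container for a whole cohort
#'
#' Extracts daily features for every subject, attaches the week-level
#' representations and labels every subject-day with the diagnostic group,
#' the responder status and the subject's maximum prescribed dose.
#'
#' @param cohort a [DigitalCohort-class].
#' @param sdType passed to [addFeatureClasses()].
#' @return A labelled [PhenotypeExperiment-class].
#' @export
buildPhenotypeExperiment <- function(cohort,
                                     sdType = c("population", "sample")) {
  daily <- do.call(rbind, lapply(cohort@sensorLogs, extractDailyFeatures))
  pe <- addFeatureClasses(daily, match.arg(sdType))
  ids <- vapply(cohort@clinicalRecords, subjectId, "")
  grp <- vapply(cohort@clinicalRecords, groupLabel, "")
  resp <- vapply(cohort@clinicalRecords, isResponder, NA)
  maxDose <- vapply(cohort@sensorLogs,
                    function(l) max(l@doseSchedule$dose_mg), 0)
  idx <- match(SummarizedExperiment::colData(pe)$subjectId, ids)
  SummarizedExperiment::colData(pe)$group <-
    factor(grp[idx], levels = c("case", "control"))
  SummarizedExperiment::colData(pe)$responder <- resp[idx]
  SummarizedExperiment::colData(pe)$max_dose_mg <- maxDose[idx]
  pe
}

#' Flatten a PhenotypeExperiment into a model-ready dataset
#'
#' The diagnosis task keeps the baseline week (week 0) of all subjects and
#' the 42 feature-by-representation columns, labelled by diagnostic group.
#' The response task keeps the treatment-period subject-days (weeks 1 and
#' later) of the case subjects, adds the two dose columns (44 columns) and
#' is labelled by responder status.
#'
#' @param pe a labelled [PhenotypeExperiment-class]
#'   (see [buildPhenotypeExperiment()]).
#' @param task `"diagnosis"` or `"response"`.
#' @return A [PhenoDataset-class].
#' @export
buildDataset <- function(pe, task = c("diagnosis", "response")) {
  task <- match.arg(task)
  cd <- SummarizedExperiment::colData(pe)
  fn <- baseFeatureNames()
  flat <- function(sel) {
    m <- cbind(t(SummarizedExperiment::assay(pe, "raw")[, sel, drop = FALSE]),
               t(SummarizedExperiment::assay(pe, "deviation")[, sel, drop = FALSE]),
               t(SummarizedExperiment::assay(pe, "weeklySD")[, sel, drop = FALSE]))
    colnames(m) <- c(paste0(fn, ".raw"), paste0(fn, ".dev"),
                     paste0(fn, ".wsd"))
    # interleave so the three representations of a feature sit together
    m[, as.vector(rbind(paste0(fn, ".raw"), paste0(fn, ".dev"),
                        paste0(fn, ".wsd"))), drop = FALSE]
  }
  if (task == "diagnosis") {
    sel <- which(cd$week == 0L)
    x <- flat(sel)
    y <- factor(as.character(cd$group[sel]), levels = c("case", "control"))
  } else {
    sel <- which(cd$group == "case" & cd$week >= 1L & !is.na(cd$responder))
    if (!length(sel))
      stop("no treatment-period case subject-days with a responder label")
    x <- cbind(flat(sel), dose_mg = cd$dose_mg[sel],
               max_dose_mg = cd$max_dose_mg[sel])
    y <- factor(ifelse(cd$responder[sel], "responder", "nonresponder"),
                levels = c("responder", "nonresponder"))
  }
  new("PhenoDataset", x = x, y = y,
      subject = as.character(cd$subjectId[sel]), task = task)
}
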