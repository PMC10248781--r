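# Plain-text interchange: JSONL event streams per subject, a cohort
# manifest, and CSV/JSON exports of feature matrices and CV results.

.isoTime <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

.writeJsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Write a cohort to disk as JSONL streams plus a manifest
#'
#' One JSONL file per stream per subject (`<id>_gps.jsonl`,
#' `<id>_gyro.jsonl`, `<id>_calls.jsonl`, `<id>_messages.jsonl`,
#' `<id>_screen.jsonl`, `<id>_daily.jsonl`), one clinical JSON per subject
#' and a cohort `manifest.csv` (subject_id, group, responder, seed).
#' Timestamps are ISO-8601 UTC.
#'
#' @param cohort a [DigitalCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort@sensorLogs)) {
    log <- cohort@sensorLogs[[i]]
    rec <- cohort@clinicalRecords[[i]]
    id <- log@subjectId
    gps <- log@gpsFixes
    .writeJsonl(lapply(seq_len(nrow(gps)), function(r)
      list(t = .isoTime(gps$timestamp[r]), lat = gps$lat[r],
           lon = gps$lon[r])), file.path(dir, paste0(id, "_gps.jsonl")))
    gyroRecs <- list()
    for (day in log@gyroBursts) {
      ts <- attr(day, "timestamps")
      for (bi in seq_len(dim(day)[1]))
        gyroRecs[[length(gyroRecs) + 1L]] <-
          list(t = .isoTime(ts[bi]), spacing = attr(day, "spacing"),
               x = day[bi, , 1], y = day[bi, , 2], z = day[bi, , 3])
    }
    .writeJsonl(gyroRecs, file.path(dir, paste0(id, "_gyro.jsonl")))
    cl <- log@callLog
    .writeJsonl(lapply(seq_len(nrow(cl)), function(r)
      list(t = .isoTime(cl$timestamp[r]), direction = cl$direction[r],
           duration_s = cl$duration_s[r], contact = cl$contact_id[r])),
      file.path(dir, paste0(id, "_calls.jsonl")))
    ml <- log@messageLog
    .writeJsonl(lapply(seq_len(nrow(ml)), function(r)
      list(t = .isoTime(ml$timestamp[r]), direction = ml$direction[r],
           char_length = ml$char_length[r], contact = ml$contact_id[r])),
      file.path(dir, paste0(id, "_messages.jsonl")))
    ss <- log@screenSessions
    .writeJsonl(lapply(seq_len(nrow(ss)), function(r)
      list(on = .isoTime(ss$on[r]), off = .isoTime(ss$off[r]))),
      file.path(dir, paste0(id, "_screen.jsonl")))
    daily <- merge(log@imageCounts, log@doseSchedule, by = "date")
    .writeJsonl(lapply(seq_len(nrow(daily)), function(r)
      list(date = format(daily$date[r]), images = daily$count[r],
           dose_mg = daily$dose_mg[r])),
      file.path(dir, paste0(id, "_daily.jsonl")))
    clin <- list(subject_id = id, group = rec@group,
                 responder = rec@responder,
                 weekly = rec@weeklyScores, baseline = rec@baselineScores)
    jsonlite::write_json(clin, file.path(dir, paste0(id, "_clinical.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  manifest <- data.frame(
    subject_id = vapply(cohort@sensorLogs, subjectId, ""),
    group = vapply(cohort@clinicalRecords, groupLabel, ""),
    responder = vapply(cohort@clinicalRecords, isResponder, NA),
    seed = cohort@spec@seed)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a flattened feature matrix as CSV with a column manifest
#'
#' @param dataset a [PhenoDataset-class].
#' @param path output CSV; a companion `<path>.columns.csv` maps each
#'   column to its base feature and representation.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(dataset, path) {
  df <- data.frame(subject_id = dataset@subject, label = dataset@y,
                   dataset@x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  cols <- colnames(dataset@x)
  parts <- strsplit(cols, ".", fixed = TRUE)
  manifest <- data.frame(
    column = cols,
    base_feature = vapply(parts, `[[`, "", 1),
    representation = vapply(parts, function(p)
      if (length(p) > 1) p[[2]] else "raw", ""))
  write.csv(manifest, paste0(path, ".columns.csv"), row.names = FALSE)
  invisible(path)
}

#' Export a CvReport to CSV and JSON
#'
#' @param report a [CvReport-class].
#' @param stem output path stem; writes `<stem>.csv` (per-repeat rows) and
#'   `<stem>.json` (repeat rows plus the overall summary).
#' @return `stem`, invisibly.
#' @export
writeCvReport <- function(report, stem) {
  write.csv(report@repeats, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(task = report@task, classifier = report@classifier,
         repeats = report@repeats,
         overall = list(mean = report@overallMean,
                        max = report@overallMax,
                        min = report@overallMin)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(stem)
}

#' Write an elimination path as CSV
#'
#' One row per (accepted step, active feature): step index, feature, its
#' NEWFM rank at that step, and the step's held-out accuracy.
#'
#' @param path an `"EliminationPath"` from [backwardEliminate()].
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
writeEliminationPath <- function(path, file) {
  rows <- do.call(rbind, lapply(seq_along(path$steps), function(i) {
    st <- path$steps[[i]]
    data.frame(step = i, feature = st$active,
               rank = unname(st$ranks[st$active]),
               accuracy = st$accuracy)
  }))
  write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
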