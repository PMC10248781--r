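#' CohortSpec: design of a synthetic passive-sensing cohort
#'
#' Describes the study design emulated by [generateCohort()]: group sizes,
#' monitoring window, per-feature base rates and between-subject dispersions,
#' and planted standardized effects. The default design is a 24-case /
#' 10-control cohort monitored for 5 weeks (7 baseline days + 4 treatment
#' weeks) with 10 treatment responders among the cases.
#'
#' Planted effects are standardized mean differences at the subject level:
#' an `effectMap` entry of `d` for feature `f` shifts the case-group mean of
#' the generator dial behind `f` by `d` between-subject standard deviations.
#' `responderEffectMap` does the same for responders relative to
#' nonresponders within the case group. `n_people_called` and
#' `n_people_messaged` have no independent dial and cannot carry an effect.
#'
#' @slot nCase,nControl,nResponder group sizes; `nResponder <= nCase`.
#' @slot daysBaseline,daysMonitoring monitoring window in days.
#' @slot effectMap named numeric, case-vs-control standardized effects.
#' @slot responderEffectMap named numeric, responder-vs-nonresponder effects.
#' @slot baseRates named numeric, daily means of the generator dials.
#' @slot dispersions named numeric, between-subject SDs of the dials.
#' @slot contactPool size of each subject's contact pool.
#' @slot seed integer master seed; all streams derive sub-seeds from it.
#'
#' @seealso [cohortSpec()] for the user constructor.
#' @export
setClass("CohortSpec",
  representation(nCase = "integer", nControl = "integer",
                 nResponder = "integer", daysBaseline = "integer",
                 daysMonitoring = "integer",
                 effectMap = "numeric", responderEffectMap = "numeric",
                 baseRates = "numeric", dispersions = "numeric",
                 contactPool = "integer", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msgs <- character()
  for (fld in c("nCase", "nControl", "nResponder", "daysBaseline",
                "daysMonitoring", "contactPool"))
    if (!isCount(slot(object, fld)))
      msgs <- c(msgs, sprintf("'%s' must be a positive integer", fld))
  if (isCount(object@nCase) && isCount(object@nResponder) &&
      object@nResponder > object@nCase)
    msgs <- c(msgs, "'nResponder' must not exceed 'nCase'")
  if (!all(names(object@baseRates) %in% .dialNames) ||
      !all(.dialNames %in% names(object@baseRates)))
    msgs <- c(msgs, "'baseRates' must name every generator dial")
  if (!all(.dialNames %in% names(object@dispersions)))
    msgs <- c(msgs, "'dispersions' must name every generator dial")
  if (any(object@dispersions <= 0))
    msgs <- c(msgs, "'dispersions' must all be > 0")
  for (mp in c("effectMap", "responderEffectMap")) {
    bad <- setdiff(names(slot(object, mp)), names(.featureDial))
    if (length(bad))
      msgs <- c(msgs, sprintf(
        "'%s' has entries for features without an independent dial: %s",
        mp, paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' SensorEventLog: one subject's raw smartphone streams
#'
#' Container for the raw event streams collected passively from one
#' subject's phone over the monitoring window: GPS fixes every 15 minutes,
#' 50-sample triaxial gyroscope bursts every 15 minutes (0.1 s spacing),
#' call and text-message records, screen on/off sessions, daily counts of
#' added image files, and the daily antidepressant dose.
#'
#' @slot subjectId character scalar.
#' @slot startDate first monitored day.
#' @slot nDays length of the monitoring window in days.
#' @slot gpsFixes data.frame with `timestamp` (POSIXct, UTC), `lat`, `lon`.
#' @slot gyroBursts list with one element per day: a `96 x 50 x 3` array of
#'   rad/s samples with attributes `timestamps` and `spacing` (seconds).
#' @slot callLog data.frame `timestamp`, `direction` ("in"/"out"),
#'   `duration_s`, `contact_id`.
#' @slot messageLog data.frame `timestamp`, `direction`, `char_length`,
#'   `contact_id`.
#' @slot screenSessions data.frame `on`, `off` (POSIXct; `off >= on`,
#'   sessions non-overlapping, split at midnight).
#' @slot imageCounts data.frame `date`, `count`.
#' @slot doseSchedule data.frame `date`, `dose_mg`.
#'
#' @aliases subjectId gpsFixes gyroBursts callLog messageLog screenSessions
#'   imageCounts doseSchedule
#' @export
setClass("SensorEventLog",
  representation(subjectId = "character", startDate = "Date",
                 nDays = "integer", gpsFixes = "data.frame",
                 gyroBursts = "list", callLog = "data.frame",
                 messageLog = "data.frame", screenSessions = "data.frame",
                 imageCounts = "data.frame", doseSchedule = "data.frame"))

.strictlyIncreasing <- function(x) length(x) < 2L || all(diff(as.numeric(x)) > 0)

setValidity("SensorEventLog", function(object) {
  msgs <- character()
  if (length(object@subjectId) != 1L)
    msgs <- c(msgs, "'subjectId' must be a single id")
  if (!.strictlyIncreasing(object@gpsFixes$timestamp))
    msgs <- c(msgs, "GPS timestamps must be strictly increasing")
  if (!.strictlyIncreasing(object@callLog$timestamp))
    msgs <- c(msgs, "call timestamps must be strictly increasing")
  if (!.strictlyIncreasing(object@messageLog$timestamp))
    msgs <- c(msgs, "message timestamps must be strictly increasing")
  if (nrow(object@callLog) && any(object@callLog$duration_s < 0))
    msgs <- c(msgs, "call durations must be >= 0")
  for (day in object@gyroBursts)
    if (!is.array(day) || length(dim(day)) != 3L || dim(day)[2] != 50L ||
        dim(day)[3] != 3L) {
      msgs <- c(msgs, "every gyroscope burst must hold exactly 50 triaxial samples")
      break
    }
  ss <- object@screenSessions
  if (nrow(ss)) {
    if (any(as.numeric(ss$off) < as.numeric(ss$on)))
      msgs <- c(msgs, "screen sessions must have off >= on")
    o <- order(ss$on)
    if (nrow(ss) > 1L &&
        any(as.numeric(ss$on[o][-1]) < as.numeric(ss$off[o][-nrow(ss)])))
      msgs <- c(msgs, "screen sessions must not overlap")
  }
  if (length(msgs)) msgs else TRUE
})

#' ClinicalRecord: weekly scale scores and labels for one subject
#'
#' Weekly clinician-rated scores (CDRS-R, CDI, C-SSRS, CGI-S, CGAS), the
#' baseline-only assessments (SCARED, IQ, FACES-IV, age, sex), the
#' diagnostic group and — for cases — the antidepressant treatment-response
#' label derived from the 40% CDRS-R decrease rule.
#'
#' @slot subjectId character scalar.
#' @slot group `"case"` (MDD) or `"control"`.
#' @slot weeklyScores data.frame `week`, `cdrsr`, `cdi`, `cssrs`, `cgis`,
#'   `cgas`; cases carry weeks 0 through 8, controls the monitored weeks.
#' @slot baselineScores named list: `scared`, `iq`, `faces`, `age`, `sex`.
#' @slot responder logical; `NA` for controls.
#'
#' @aliases groupLabel weeklyScores baselineScores isResponder
#' @export
setClass("ClinicalRecord",
  representation(subjectId = "character", group = "character",
                 weeklyScores = "data.frame", baselineScores = "list",
                 responder = "logical"))

setValidity("ClinicalRecord", function(object) {
  msgs <- character()
  if (!object@group %in% c("case", "control"))
    msgs <- c(msgs, "'group' must be \"case\" or \"control\"")
  ws <- object@weeklyScores
  cd <- ws$cdrsr[!is.na(ws$cdrsr)]
  if (length(cd) && (any(cd < .cdrsrRange[1]) || any(cd > .cdrsrRange[2])))
    msgs <- c(msgs, "CDRS-R scores must lie in [17, 113]")
  if (identical(object@group, "case") &&
      !all(c(0, 8) %in% ws$week))
    msgs <- c(msgs, "cases must carry CDRS-R at baseline (week 0) and week 8")
  if (length(msgs)) msgs else TRUE
})

#' DigitalCohort: paired sensor logs and clinical records
#'
#' The unit handed from the generator to feature extraction: one
#' [SensorEventLog-class] and one [ClinicalRecord-class] per subject, plus
#' the [CohortSpec-class] that produced them.
#'
#' @slot sensorLogs list of [SensorEventLog-class].
#' @slot clinicalRecords list of [ClinicalRecord-class], same order.
#' @slot spec the generating [CohortSpec-class].
#'
#' @aliases sensorLogs clinicalRecords
#' @export
setClass("DigitalCohort",
  representation(sensorLogs = "list", clinicalRecords = "list",
                 spec = "CohortSpec"))

setValidity("DigitalCohort", function(object) {
  if (length(object@sensorLogs) != length(object@clinicalRecords))
    return("sensor logs and clinical records must pair one-to-one")
  ids1 <- vapply(object@sensorLogs, function(x) x@subjectId, "")
  ids2 <- vapply(object@clinicalRecords, function(x) x@subjectId, "")
  if (!identical(ids1, ids2))
    return("sensor logs and clinical records must list the same subjects")
  TRUE
})

#' PhenotypeExperiment: daily feature matrix with three representations
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the daily
#' behavioural features: rows are the 14 base features, columns are
#' subject-days, and the three assays are the per-feature representations
#' used downstream — `raw` (the daily value), `deviation` (absolute
#' deviation from the subject-week mean) and `weeklySD` (the subject-week
#' standard deviation, constant within a week). `colData` carries
#' `subjectId`, `date`, `day`, `week`, the dose columns and, once labels are
#' attached, `group` and `responder`.
#'
#' @export
#' @import SummarizedExperiment
setClass("PhenotypeExperiment", contains = "SummarizedExperiment")

setValidity("PhenotypeExperiment", function(object) {
  msgs <- character()
  need <- c("raw", "deviation", "weeklySD")
  if (!all(need %in% SummarizedExperiment::assayNames(object)))
    msgs <- c(msgs, "assays 'raw', 'deviation' and 'weeklySD' are required")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("subjectId", "date", "day", "week"))
    if (!col %in% colnames(cd))
      msgs <- c(msgs, sprintf("colData column '%s' is required", col))
  if (length(msgs)) msgs else TRUE
})

#' PhenoDataset: a model-ready design matrix for one learning task
#'
#' Flattened view of a [PhenotypeExperiment-class] for one task: rows are
#' subject-days, columns are feature-by-representation values (42 columns
#' for the diagnosis task, 44 with the two dose features for the response
#' task), `y` is the class label and `subject` tags every row for
#' subject-level fold assignment.
#'
#' @slot x numeric matrix, subject-days by features.
#' @slot y factor with two levels (first level is the tie-break class).
#' @slot subject character, one id per row.
#' @slot task `"diagnosis"` or `"response"`.
#' @export
setClass("PhenoDataset",
  representation(x = "matrix", y = "factor", subject = "character",
                 task = "character"))

setValidity("PhenoDataset", function(object) {
  msgs <- character()
  if (nrow(object@x) != length(object@y) ||
      nrow(object@x) != length(object@subject))
    msgs <- c(msgs, "'x', 'y' and 'subject' must agree in length")
  if (nlevels(object@y) != 2L)
    msgs <- c(msgs, "'y' must have exactly two levels")
  if (length(msgs)) msgs else TRUE
})

#' WfmModel: weighted fuzzy membership functions for two classes
#'
#' The NEWFM model state: for every feature and each of the two classes,
#' `m` triangular membership functions (apex within the scaled feature
#' range, feet at the neighbouring apexes) with weights in `[0, 1]`, plus
#' the min-max scaler fitted on the training data. Class-conditional
#' membership of a value is the bounded sum (capped at 1) of the weighted
#' triangles, and features are scored by the non-overlapping area between
#' the two class curves.
#'
#' @slot features feature names (column order of the training matrix).
#' @slot classes the two class labels; `classes[1]` is the tie-break class.
#' @slot apex,weight named lists with one `m x p` matrix per class.
#' @slot scaler list with per-feature `min` and `range` of the training data.
#' @slot degenerate logical per feature; `TRUE` when the training values
#'   were constant (flat membership, zero discrimination).
#' @slot config list of training settings (`m`, `alpha`, `beta`, `epochs`).
#' @export
setClass("WfmModel",
  representation(features = "character", classes = "character",
                 apex = "list", weight = "list", scaler = "list",
                 degenerate = "logical", config = "list"))

setValidity("WfmModel", function(object) {
  msgs <- character()
  if (length(object@classes) != 2L)
    msgs <- c(msgs, "exactly two classes are supported")
  for (cl in names(object@weight)) {
    w <- object@weight[[cl]]
    if (any(w < 0 | w > 1)) msgs <- c(msgs, "weights must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' CvReport: subject-level repeated k-fold results
#'
#' Result container for [runRepeatedCv()]: one row per repeat with the k
#' held-out fold accuracies, their mean, and the mean training accuracy;
#' the overall mean, maximum and minimum of the repeat means; and the NEWFM
#' elimination paths collected across folds for averaged-rank importance.
#'
#' @slot task,classifier character labels.
#' @slot repeats data.frame with columns `repeatId`, `acc1` ... `acck`,
#'   `meanTest`, `meanTrain`.
#' @slot overallMean,overallMax,overallMin summary of the repeat means.
#' @slot paths list of elimination paths (one per fold and repeat).
#' @slot folds list of per-repeat fold assignments (subject -> fold).
#'
#' @aliases repeatSummary cvPaths
#' @export
setClass("CvReport",
  representation(task = "character", classifier = "character",
                 repeats = "data.frame", overallMean = "numeric",
                 overallMax = "numeric", overallMin = "numeric",
                 paths = "list", folds = "list"))

setValidity("CvReport", function(object) {
  msgs <- character()
  accCols <- grep("^(acc[0-9]+|meanTest|meanTrain)$",
                  colnames(object@repeats), value = TRUE)
  accs <- unlist(object@repeats[accCols])
  if (length(accs) && (any(accs < 0, na.rm = TRUE) ||
                       any(accs > 1, na.rm = TRUE)))
    msgs <- c(msgs, "accuracies must lie in [0, 1]")
  if (length(object@repeats$meanTest) &&
      !(object@overallMin <= object@overallMean + 1e-12 &&
        object@overallMean <= object@overallMax + 1e-12))
    msgs <- c(msgs, "overall min <= mean <= max must hold")
  if (length(msgs)) msgs else TRUE
})

## ---- accessors -----------------------------------------------------------

#' @rdname SensorEventLog-class
#' @param x an object of the documented class.
#' @export
setMethod("subjectId", "SensorEventLog", function(x) x@subjectId)
#' @rdname ClinicalRecord-class
#' @param x an object of the documented class.
#' @export
setMethod("subjectId", "ClinicalRecord", function(x) x@subjectId)
#' @rdname SensorEventLog-class
#' @export
setMethod("gpsFixes", "SensorEventLog", function(x) x@gpsFixes)
#' @rdname SensorEventLog-class
#' @export
setMethod("gyroBursts", "SensorEventLog", function(x) x@gyroBursts)
#' @rdname SensorEventLog-class
#' @export
setMethod("callLog", "SensorEventLog", function(x) x@callLog)
#' @rdname SensorEventLog-class
#' @export
setMethod("messageLog", "SensorEventLog", function(x) x@messageLog)
#' @rdname SensorEventLog-class
#' @export
setMethod("screenSessions", "SensorEventLog", function(x) x@screenSessions)
#' @rdname SensorEventLog-class
#' @export
setMethod("imageCounts", "SensorEventLog", function(x) x@imageCounts)
#' @rdname SensorEventLog-class
#' @export
setMethod("doseSchedule", "SensorEventLog", function(x) x@doseSchedule)

#' @rdname ClinicalRecord-class
#' @export
setMethod("groupLabel", "ClinicalRecord", function(x) x@group)
#' @rdname ClinicalRecord-class
#' @export
setMethod("weeklyScores", "ClinicalRecord", function(x) x@weeklyScores)
#' @rdname ClinicalRecord-class
#' @export
setMethod("baselineScores", "ClinicalRecord", function(x) x@baselineScores)
#' @rdname ClinicalRecord-class
#' @export
setMethod("isResponder", "ClinicalRecord", function(x) x@responder)

#' @rdname DigitalCohort-class
#' @param x an object of the documented class.
#' @export
setMethod("sensorLogs", "DigitalCohort", function(x) x@sensorLogs)
#' @rdname DigitalCohort-class
#' @export
setMethod("clinicalRecords", "DigitalCohort", function(x) x@clinicalRecords)

#' @rdname CvReport-class
#' @param x an object of the documented class.
#' @export
setMethod("repeatSummary", "CvReport", function(x) x@repeats)
#' @rdname CvReport-class
#' @export
setMethod("cvPaths", "CvReport", function(x) x@paths)

## ---- show methods --------------------------------------------------------

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d cases (%d responders) / %d controls, %d days (%d baseline)\n",
              object@nCase, object@nResponder, object@nControl,
              object@daysMonitoring, object@daysBaseline))
  if (length(object@effectMap))
    cat("  case-vs-control effects:",
        paste(sprintf("%s=%.2g", names(object@effectMap), object@effectMap),
              collapse = ", "), "\n")
  if (length(object@responderEffectMap))
    cat("  responder effects:",
        paste(sprintf("%s=%.2g", names(object@responderEffectMap),
                      object@responderEffectMap), collapse = ", "), "\n")
  cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "SensorEventLog", function(object) {
  cat(sprintf("SensorEventLog '%s': %d days from %s\n", object@subjectId,
              object@nDays, format(object@startDate)))
  cat(sprintf("  %d GPS fixes, %d gyro burst-days, %d calls, %d messages, %d screen sessions\n",
              nrow(object@gpsFixes), length(object@gyroBursts),
              nrow(object@callLog), nrow(object@messageLog),
              nrow(object@screenSessions)))
})

setMethod("show", "ClinicalRecord", function(object) {
  resp <- if (is.na(object@responder)) "n/a"
          else if (object@responder) "responder" else "nonresponder"
  cat(sprintf("ClinicalRecord '%s' (%s, %s): %d weekly assessments\n",
              object@subjectId, object@group, resp,
              nrow(object@weeklyScores)))
})

setMethod("show", "DigitalCohort", function(object) {
  grp <- vapply(object@clinicalRecords, function(r) r@group, "")
  cat(sprintf("DigitalCohort: %d subjects (%d case / %d control)\n",
              length(object@sensorLogs), sum(grp == "case"),
              sum(grp == "control")))
})

setMethod("show", "PhenoDataset", function(object) {
  cat(sprintf("PhenoDataset (%s): %d rows x %d features, %d subjects; classes %s\n",
              object@task, nrow(object@x), ncol(object@x),
              length(unique(object@subject)),
              paste(sprintf("%s=%d", levels(object@y), table(object@y)),
                    collapse = ", ")))
})

setMethod("show", "WfmModel", function(object) {
  cat(sprintf("WfmModel: %d features x 2 classes (%s), %d membership functions each\n",
              length(object@features), paste(object@classes, collapse = " vs "),
              object@config$m))
})

setMethod("show", "CvReport", function(object) {
  cat(sprintf("CvReport (%s, %s): %d repeats of subject-level %d-fold CV\n",
              object@task, object@classifier, nrow(object@repeats),
              sum(grepl("^acc[0-9]+$", colnames(object@repeats)))))
  cat(sprintf("  mean test accuracy %.3f (min %.3f, max %.3f); mean training accuracy %.3f\n",
              object@overallMean, object@overallMin, object@overallMax,
              mean(object@repeats$meanTrain)))
})
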