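#' @rdname SensorEventLog-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname SensorEventLog-class
#' @export
setGeneric("gpsFixes", function(x) standardGeneric("gpsFixes"))

#' @rdname SensorEventLog-class
#' @export
setGeneric("gyroBursts", function(x) standardGeneric("gyroBursts"))

#' @rdname SensorEventLog-class
#' @export
setGeneric("callLog", function(x) standardGeneric("callLog"))

#' @rdname SensorEventLog-class
#' @export
setGeneric("messageLog", function(x) standardGeneric("messageLog"))

#' @rdname SensorEventLog-class
#' @export
setGeneric("screenSessions", function(x) standardGeneric("screenSessions"))

#' @rdname SensorEventLog-class
#' @export
setGeneric("imageCounts", function(x) standardGeneric("imageCounts"))

#' @rdname SensorEventLog-class
#' @export
setGeneric("doseSchedule", function(x) standardGeneric("doseSchedule"))

#' @rdname ClinicalRecord-class
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname ClinicalRecord-class
#' @export
setGeneric("weeklyScores", function(x) standardGeneric("weeklyScores"))

#' @rdname ClinicalRecord-class
#' @export
setGeneric("baselineScores", function(x) standardGeneric("baselineScores"))

#' @rdname ClinicalRecord-class
#' @export
setGeneric("isResponder", function(x) standardGeneric("isResponder"))

#' @rdname DigitalCohort-class
#' @export
setGeneric("sensorLogs", function(x) standardGeneric("sensorLogs"))

#' @rdname DigitalCohort-class
#' @export
setGeneric("clinicalRecords", function(x) standardGeneric("clinicalRecords"))

#' @rdname CvReport-class
#' @export
setGeneric("repeatSummary", function(x) standardGeneric("repeatSummary"))

#' @rdname CvReport-class
#' @export
setGeneric("cvPaths", function(x) standardGeneric("cvPaths"))
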