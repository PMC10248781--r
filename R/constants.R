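#' Names of the 14 base daily behavioural features
#'
#' The daily feature vector extracted from one subject-day of raw smartphone
#' streams: screen use, call and text-message summaries, GPS movement
#' distance, gyroscope momentum and the daily count of added image files.
#' Dose features (`dose_mg`, `max_dose_mg`) are additional columns used only
#' by the treatment-response task and are not part of this set.
#'
#' @return Character vector of length 14.
#' @export
#' @examples
#' baseFeatureNames()
baseFeatureNames <- function() {
  c("screen_usage_duration",
    "total_time_calls_made",
    "total_time_calls_received",
    "n_calls_received",
    "n_calls_sent",
    "n_people_called",
    "movement_distance",
    "momentum",
    "n_people_messaged",
    "n_messages_received",
    "n_messages_sent",
    "total_length_messages_received",
    "total_length_messages_sent",
    "added_image_files")
}

# generator dials: one independent knob per plantable feature
.dialNames <- c("screen_min", "distance_km", "gyro_sd",
                "calls_received", "calls_sent",
                "messages_received", "messages_sent", "images",
                "call_time_made_s", "call_time_received_s",
                "msg_len_received", "msg_len_sent")

# base feature -> generator dial; n_people_* have no independent dial (they
# emerge from contact-pool draws) and therefore cannot carry a planted effect
.featureDial <- c(
  screen_usage_duration          = "screen_min",
  movement_distance              = "distance_km",
  momentum                       = "gyro_sd",
  n_calls_received               = "calls_received",
  n_calls_sent                   = "calls_sent",
  n_messages_received            = "messages_received",
  n_messages_sent                = "messages_sent",
  added_image_files              = "images",
  total_time_calls_made          = "call_time_made_s",
  total_time_calls_received      = "call_time_received_s",
  total_length_messages_received = "msg_len_received",
  total_length_messages_sent     = "msg_len_sent")

.kmPerDegree <- 6371 * pi / 180  # great-circle km per degree at R = 6371 km

.cdrsrRange <- c(17, 113)

# Frozen validation study conditions for planted-effect recovery checks:
# a single dominant feature against 13 null features, and a wide graded
# effect ladder over the 8 mutually decoupled generator dials.
.dominantEffectMap <- c(momentum = 3.0)

.ladderEffectMap <- c(momentum = 4.0, screen_usage_duration = 2.0,
                      movement_distance = 1.6,
                      total_time_calls_received = 1.2,
                      total_time_calls_made = 0.9,
                      total_length_messages_received = 0.6,
                      total_length_messages_sent = 0.3,
                      added_image_files = 0.15)
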