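#' The 66-feature registry
#'
#' The frozen library of digital-biomarker features extracted per session:
#' 13 visual, 28 acoustic, and 25 text features. Each feature carries its
#' modality and the temporal aggregation used to compute it (per second,
#' per frame, per response, or per detected event).
#'
#' The visual names follow the implemented-feature names of the evidence
#' tables (affect measure, mouth curvature, gaze distributions, blink/yawn
#' event statistics, ...). The acoustic and text registries realize every
#' named stem (pitch, vol, ealvi, jitter, shimmer, timbre, formant, pauses;
#' words per second, response latency, transcript length, complexity,
#' sentiment, hesitations, ...) expanded to the printed modality counts and
#' frozen so the 13/28/25 partition is meaningful.
#'
#' @return A data.frame with columns `feature`, `modality`
#'   ("visual"/"audio"/"text") and `aggregation`.
#' @export
#' @examples
#' table(featureRegistry()$modality)
featureRegistry <- function() {
  vis <- data.frame(
    feature = c("affect_measure", "mouth_curvature", "eyebrow_droop",
                "gaze_down_dist", "gaze_x_dist", "gaze_y_dist",
                "movement_speech_measure", "eyelid_droop",
                "blinks_per_s", "blink_len", "yawns_per_s", "yawn_len",
                "eye_movements_per_s"),
    modality = "visual",
    aggregation = c("per_frame", "per_frame", "per_frame",
                    "per_frame", "per_frame", "per_frame",
                    "per_second", "per_frame",
                    "per_second", "per_event", "per_second", "per_event",
                    "per_second"),
    stringsAsFactors = FALSE)
  aud <- data.frame(
    feature = c("pitch_mean", "pitch_std", "pitch_range", "pitch_slope",
                "vol_mean", "vol_std", "vol_range", "vol_slope", "ealvi",
                "jitter_local", "jitter_rap", "shimmer_local", "shimmer_db",
                "hnr_mean",
                "spectral_centroid_mean", "spectral_centroid_std",
                "spectral_bandwidth_mean", "spectral_flatness_mean",
                "spectral_rolloff_mean",
                "f1_mean", "f2_mean", "f3_mean", "f1_std", "f2_std",
                "f2_f1_ratio",
                "pause_rate", "pause_mean_len", "voiced_fraction"),
    modality = "audio",
    aggregation = c(rep("per_response", 14L),
                    rep("per_response", 5L),
                    rep("per_response", 6L),
                    "per_second", "per_event", "per_response"),
    stringsAsFactors = FALSE)
  txt <- data.frame(
    feature = c("words_per_s", "response_latency_mean", "response_latency_std",
                "transcript_len_words", "mean_response_len_words",
                "ari_complexity", "fk_complexity", "gunning_fog_complexity",
                "sentiment_mean", "sentiment_std", "emotion_keyword_prop",
                "positive_emotion_prop", "negative_emotion_prop",
                "hesitations_per_s", "hesitation_prop",
                "transcript_pause_rate", "transcript_pause_mean_len",
                "type_token_ratio", "mean_word_len", "mean_sentence_len",
                "first_person_singular_prop", "negation_prop",
                "content_word_prop", "syllables_per_word", "long_word_prop"),
    modality = "text",
    aggregation = c("per_second", "per_response", "per_response",
                    "per_response", "per_response",
                    "per_response", "per_response", "per_response",
                    "per_response", "per_response", "per_response",
                    "per_response", "per_response",
                    "per_second", "per_response",
                    "per_second", "per_event",
                    "per_response", "per_response", "per_response",
                    "per_response", "per_response",
                    "per_response", "per_response", "per_response"),
    stringsAsFactors = FALSE)
  out <- rbind(vis, aud, txt)
  rownames(out) <- out$feature
  out
}

#' Feature names for one modality
#'
#' @param modality One of "visual", "audio", "text", or "all".
#' @return Character vector of feature names.
#' @export
featureNames66 <- function(modality = c("all", "visual", "audio", "text")) {
  modality <- match.arg(modality)
  reg <- featureRegistry()
  if (modality == "all") reg$feature else reg$feature[reg$modality == modality]
}
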