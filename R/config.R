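#' Default extraction configuration
#'
#' Every tunable threshold of the extraction pipeline in one nested list,
#' serializable to/from YAML. Values are the package defaults:
#'
#' * `temporal`: `target_fps` 30 frames/s (landmark grid), `target_rate`
#'   22050 Hz (audio analysis rate).
#' * `visual`: blink hysteresis `blink_on` 0.5 / `blink_off` 0.3 with event
#'   duration bounds 66-500 ms; yawn `jawOpen` threshold 0.6 sustained >=
#'   1.5 s; saccade detection at gaze-velocity peaks > 3 x median absolute
#'   velocity with 100 ms minimum separation.
#' * `audio`: 2048-sample analysis windows with 512-sample hop; f0 search
#'   range 75-500 Hz; voicing periodicity threshold 0.45; silence threshold
#'   -40 dB relative to the response's peak frame RMS; minimum pause 300 ms;
#'   LPC order 12 for formants at the 11,025 Hz formant analysis rate;
#'   85% spectral rolloff.
#' * `text`: 0.5 s minimum inter-word gap for transcript pauses; filler
#'   lexicon \{um, uh, er, ah, hmm, mhm, uhm\}.
#'
#' @return Nested named list of parameters.
#' @export
defaultConfig <- function() {
  list(
    temporal = list(target_fps = 30, target_rate = 22050),
    visual = list(
      blink_on = 0.5, blink_off = 0.3,
      blink_min_dur = 0.066, blink_max_dur = 0.5,
      yawn_open = 0.6, yawn_min_dur = 1.5,
      saccade_median_mult = 3, saccade_min_sep = 0.1),
    audio = list(
      frame_length = 2048L, hop_length = 512L,
      f_min = 75, f_max = 500, voicing_threshold = 0.45,
      silence_db = -40, min_pause = 0.3,
      lpc_order = 12L, formant_rate = 11025, rolloff_quantile = 0.85),
    text = list(
      gap_min = 0.5,
      fillers = c("um", "uh", "er", "ah", "hmm", "mhm", "uhm")))
}

#' Load a configuration file, merged over the defaults
#'
#' @param path Path to a YAML file containing any subset of the keys of
#'   [defaultConfig()]; omitted keys keep their defaults. `NULL` returns the
#'   defaults.
#' @return Nested named list of parameters.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  mergeList(cfg, user)
}

mergeList <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]])) {
      base[[k]] <- mergeList(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}
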