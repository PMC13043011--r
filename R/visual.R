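## Visual features from the interpolated blendshape/landmark stream:
## blink & yawn event detection, gaze distribution, eyelid droop, and the
## expressivity measures. 13 features total (see featureRegistry()).

## hysteresis event detector over a per-frame activation signal; end of an
## event is the time of the first frame back below thetaOff
detectEvents <- function(tt, sig, thetaOn, thetaOff, minDur, maxDur) {
  events <- data.frame(start = numeric(), end = numeric())
  inEvent <- FALSE
  start <- NA_real_
  for (i in seq_along(sig)) {
    if (!inEvent && sig[i] >= thetaOn) {
      inEvent <- TRUE
      start <- tt[i]
    } else if (inEvent && sig[i] < thetaOff) {
      events <- rbind(events, data.frame(start = start, end = tt[i]))
      inEvent <- FALSE
    }
  }
  if (inEvent) events <- rbind(events, data.frame(start = start,
                                                  end = tt[length(tt)]))
  dur <- events$end - events$start
  events[dur >= minDur & dur <= maxDur, , drop = FALSE]
}

#' Detect blink events
#'
#' A blink is an excursion of the mean of the `eyeBlinkLeft`/`eyeBlinkRight`
#' blendshapes above an onset threshold, ended with hysteresis when the
#' signal falls back below the offset threshold; events outside the
#' physiological duration bounds are discarded.
#'
#' @param stream An interpolated [LandmarkStream].
#' @param config Configuration list, see [defaultConfig()] (`$visual`).
#' @return data.frame with columns `kind` ("blink"), `start`, `end` (s).
#' @export
detectBlinks <- function(stream, config = defaultConfig()) {
  if (nFrames(stream) == 0L) stop("cannot detect blinks in an empty stream")
  v <- config$visual
  bs <- blendshapes(stream)
  sig <- rowMeans(bs[, c("eyeBlinkLeft", "eyeBlinkRight"), drop = FALSE])
  ev <- detectEvents(frameTimes(stream), sig, v$blink_on, v$blink_off,
                     v$blink_min_dur, v$blink_max_dur)
  if (nrow(ev)) cbind(kind = "blink", ev) else
    data.frame(kind = character(), start = numeric(), end = numeric())
}

#' Detect yawn events
#'
#' A yawn is a sustained `jawOpen` activation above threshold lasting at
#' least the configured minimum duration (default 1.5 s).
#'
#' @inheritParams detectBlinks
#' @return data.frame with columns `kind` ("yawn"), `start`, `end` (s).
#' @export
detectYawns <- function(stream, config = defaultConfig()) {
  if (nFrames(stream) == 0L) stop("cannot detect yawns in an empty stream")
  v <- config$visual
  sig <- blendshapes(stream)[, "jawOpen"]
  ev <- detectEvents(frameTimes(stream), sig, v$yawn_open, v$yawn_open,
                     v$yawn_min_dur, Inf)
  if (nrow(ev)) cbind(kind = "yawn", ev) else
    data.frame(kind = character(), start = numeric(), end = numeric())
}

#' Eyelid droop score
#'
#' Mean of the `eyeBlinkLeft`/`eyeBlinkRight` blendshape pair over all
#' frames outside detected blink events; higher values indicate droopier
#' eyelids (partially closed eyes at rest).
#'
#' @inheritParams detectBlinks
#' @param blinkEvents Blink events from [detectBlinks()] to mask out.
#' @return Scalar droop score.
#' @export
eyelidDroop <- function(stream, blinkEvents = NULL,
                        config = defaultConfig()) {
  if (nFrames(stream) == 0L) stop("empty stream")
  if (is.null(blinkEvents)) blinkEvents <- detectBlinks(stream, config)
  tt <- frameTimes(stream)
  keep <- rep(TRUE, length(tt))
  for (i in seq_len(nrow(blinkEvents))) {
    keep[tt >= blinkEvents$start[i] & tt < blinkEvents$end[i]] <- FALSE
  }
  if (!any(keep)) stop("stream lies entirely within blink events")
  bs <- blendshapes(stream)
  mean(rowMeans(bs[keep, c("eyeBlinkLeft", "eyeBlinkRight"), drop = FALSE]))
}

## per-frame gaze direction from the eye-look blendshape quadruples;
## horizontal: positive = gaze toward the subject's right;
## vertical: positive = downward
gazeSignal <- function(bs) {
  h <- (bs[, "eyeLookInLeft"] + bs[, "eyeLookOutRight"]) / 2 -
       (bs[, "eyeLookOutLeft"] + bs[, "eyeLookInRight"]) / 2
  v <- (bs[, "eyeLookDownLeft"] + bs[, "eyeLookDownRight"]) / 2 -
       (bs[, "eyeLookUpLeft"] + bs[, "eyeLookUpRight"]) / 2
  cbind(h = h, v = v)
}

#' Gaze distribution features
#'
#' Per-frame gaze direction is derived from the eye-look blendshape
#' quadruples (nasal/temporal for horizontal, down minus up for vertical).
#' `gaze_x_dist` / `gaze_y_dist` are the mean absolute deviations from
#' centered gaze per axis; `gaze_down_dist` is the mean of the positive
#' downward component only (upward gaze does not count).
#'
#' @inheritParams detectBlinks
#' @return Named numeric: `gaze_down_dist`, `gaze_x_dist`, `gaze_y_dist`.
#' @export
gazeFeatures <- function(stream) {
  if (nFrames(stream) == 0L) stop("empty stream")
  g <- gazeSignal(blendshapes(stream))
  c(gaze_down_dist = mean(pmax(g[, "v"], 0)),
    gaze_x_dist = mean(abs(g[, "h"])),
    gaze_y_dist = mean(abs(g[, "v"])))
}

## blendshape subset used for the affect measure: everything except the
## eye-look and eye-blink groups, whose dynamics reflect gaze, not affect
expressionSubset <- function() {
  nm <- blendshapeNames()
  nm[!grepl("^eyeLook|^eyeBlink", nm)]
}

#' Expressivity and movement features
#'
#' * `affect_measure`: mean temporal standard deviation over the expression
#'   blendshape subset (all blendshapes excluding the eye-look and
#'   eye-blink groups); lower = flatter affect.
#' * `mouth_curvature`: mean smile-pair activation minus mean frown-pair
#'   activation.
#' * `eyebrow_droop`: mean of `browDownLeft`/`browDownRight`.
#' * `movement_speech_measure`: mean landmark displacement per second in
#'   the x-y plane, restricted to participant speech segments; `NA` when
#'   no speech segments are supplied.
#' * `eye_movements_per_s`: rate of gaze-velocity peaks above the saccade
#'   threshold (3 x median absolute velocity, 100 ms minimum separation).
#'
#' @inheritParams detectBlinks
#' @param speechSegments data.frame with `start`, `end` columns (seconds) of
#'   participant-speaking intervals, or `NULL`.
#' @return Named numeric vector of the five features.
#' @export
expressivityFeatures <- function(stream, speechSegments = NULL,
                                 config = defaultConfig()) {
  if (nFrames(stream) == 0L) stop("empty stream")
  bs <- blendshapes(stream)
  tt <- frameTimes(stream)
  dur <- tt[length(tt)] - tt[1]

  affect <- mean(apply(bs[, expressionSubset(), drop = FALSE], 2, stats::sd))
  if (nrow(bs) < 2L) affect <- 0
  curvature <- mean(bs[, c("mouthSmileLeft", "mouthSmileRight")]) -
    mean(bs[, c("mouthFrownLeft", "mouthFrownRight")])
  browDroop <- mean(bs[, c("browDownLeft", "browDownRight")])

  movement <- NA_real_
  if (!is.null(speechSegments) && nrow(speechSegments)) {
    lm <- landmarks(stream)
    inSpeech <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(speechSegments))) {
      inSpeech[tt >= speechSegments$start[i] &
               tt <= speechSegments$end[i]] <- TRUE
    }
    pair <- which(inSpeech[-length(tt)] & inSpeech[-1])
    if (length(pair)) {
      dx <- lm[pair + 1L, , 1, drop = FALSE] - lm[pair, , 1, drop = FALSE]
      dy <- lm[pair + 1L, , 2, drop = FALSE] - lm[pair, , 2, drop = FALSE]
      disp <- rowMeans(sqrt(dx^2 + dy^2))    # mean over landmarks, per step
      dt <- tt[pair + 1L] - tt[pair]
      movement <- sum(disp) / sum(dt)
    } else movement <- 0
  }

  eyeRate <- 0
  if (length(tt) >= 2L && dur > 0) {
    g <- gazeSignal(bs)
    dt <- diff(tt)
    vel <- sqrt(diff(g[, "h"])^2 + diff(g[, "v"])^2) / dt
    ## absolute floor keeps fp residue from counting as saccades when the
    ## median velocity is 0 (static gaze)
    thr <- max(config$visual$saccade_median_mult * stats::median(vel), 1e-6)
    hot <- vel > thr
    if (any(hot)) {
      starts <- tt[which(hot & !c(FALSE, hot[-length(hot)]))]
      if (length(starts) > 1L) {
        keep <- c(TRUE, diff(starts) >= config$visual$saccade_min_sep)
        starts <- starts[keep]
      }
      eyeRate <- length(starts) / dur
    }
  }

  c(affect_measure = affect, mouth_curvature = curvature,
    eyebrow_droop = browDroop, movement_speech_measure = movement,
    eye_movements_per_s = eyeRate)
}

#' Extract the 13 visual features of a session
#'
#' Interpolates the stream to the configured uniform frame rate if it is
#' not already uniform, detects blink and yawn events, and assembles the
#' full visual feature set. Per-second rates use the interpolated stream
#' duration as denominator. Features undefined on degenerate input (e.g.
#' `blink_len` with no blinks) are reported as `NA`, never silently zero.
#'
#' @param stream A [LandmarkStream] (raw or already interpolated).
#' @param transcript Optional [Transcript]; participant turn spans define
#'   the speech segments for `movement_speech_measure`.
#' @param config Configuration list, see [defaultConfig()].
#' @return Named numeric vector with the 13 visual feature names of
#'   [featureRegistry()].
#' @export
extractVisual <- function(stream, transcript = NULL,
                          config = defaultConfig()) {
  if (nFrames(stream) < 2L) stop("visual extraction requires >= 2 frames")
  stream <- interpolateStream(stream, config$temporal$target_fps)
  tt <- frameTimes(stream)
  dur <- tt[length(tt)] - tt[1]

  blinks <- detectBlinks(stream, config)
  yawns <- detectYawns(stream, config)
  segs <- NULL
  if (!is.null(transcript)) {
    pt <- participantTurns(transcript)
    if (nrow(pt)) segs <- data.frame(start = pt$start, end = pt$end)
  }
  expr <- expressivityFeatures(stream, segs, config)

  out <- c(
    expr[c("affect_measure", "mouth_curvature", "eyebrow_droop")],
    gazeFeatures(stream),
    expr["movement_speech_measure"],
    eyelid_droop = eyelidDroop(stream, blinks, config),
    blinks_per_s = if (dur > 0) nrow(blinks) / dur else NA_real_,
    blink_len = if (nrow(blinks)) mean(blinks$end - blinks$start) else NA_real_,
    yawns_per_s = if (dur > 0) nrow(yawns) / dur else NA_real_,
    yawn_len = if (nrow(yawns)) mean(yawns$end - yawns$start) else NA_real_,
    expr["eye_movements_per_s"])
  names(out) <- featureNames66("visual")
  out
}
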