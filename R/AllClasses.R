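#' Canonical blendshape names
#'
#' The 52 ARKit-style face blendshape activations emitted per frame by the
#' face landmarker, in canonical order. Scores are unitless activations in
#' \[0, 1\].
#'
#' @return Character vector of length 52.
#' @export
#' @examples
#' length(blendshapeNames())
blendshapeNames <- function() {
  c("eyeBlinkLeft", "eyeBlinkRight",
    "eyeLookDownLeft", "eyeLookDownRight", "eyeLookInLeft", "eyeLookInRight",
    "eyeLookOutLeft", "eyeLookOutRight", "eyeLookUpLeft", "eyeLookUpRight",
    "eyeSquintLeft", "eyeSquintRight", "eyeWideLeft", "eyeWideRight",
    "jawForward", "jawLeft", "jawRight", "jawOpen",
    "mouthClose", "mouthFunnel", "mouthPucker", "mouthLeft", "mouthRight",
    "mouthSmileLeft", "mouthSmileRight", "mouthFrownLeft", "mouthFrownRight",
    "mouthDimpleLeft", "mouthDimpleRight", "mouthStretchLeft", "mouthStretchRight",
    "mouthRollLower", "mouthRollUpper", "mouthShrugLower", "mouthShrugUpper",
    "mouthPressLeft", "mouthPressRight", "mouthLowerDownLeft", "mouthLowerDownRight",
    "mouthUpperUpLeft", "mouthUpperUpRight",
    "browDownLeft", "browDownRight", "browInnerUp", "browOuterUpLeft", "browOuterUpRight",
    "cheekPuff", "cheekSquintLeft", "cheekSquintRight",
    "noseSneerLeft", "noseSneerRight",
    "tongueOut")
}

#' Number of face-mesh landmark points per frame
#' @return Integer, 478.
#' @export
landmarkCount <- function() 478L

## ---------------------------------------------------------------------------
## AudioTrack
## ---------------------------------------------------------------------------

#' @rdname AudioTrack
#' @export
setClass("AudioTrack",
  representation(samples = "numeric", sampleRate = "numeric",
                 responseIndex = "integer"))

setValidity("AudioTrack", function(object) {
  msg <- character()
  if (length(object@samples) < 1L) msg <- c(msg, "samples must be non-empty")
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0) {
    msg <- c(msg, "sampleRate must be a single positive number")
  }
  if (length(object@samples) &&
      (max(abs(object@samples), na.rm = TRUE) > 1 + 1e-6)) {
    msg <- c(msg, "samples must lie in [-1, 1]")
  }
  if (length(object@responseIndex) != 1L || is.na(object@responseIndex) ||
      object@responseIndex < 1L) {
    msg <- c(msg, "responseIndex must be a single positive integer")
  }
  if (length(msg)) msg else TRUE
})

#' Mono audio for one participant response
#'
#' @param samples Numeric amplitude series in \[-1, 1\].
#' @param sampleRate Sampling frequency in Hz.
#' @param responseIndex 1-based participant-turn number.
#' @return An `AudioTrack` object.
#' @export
#' @examples
#' AudioTrack(sin(2 * pi * 220 * seq(0, 1, by = 1 / 8000)), 8000)
AudioTrack <- function(samples, sampleRate, responseIndex = 1L) {
  new("AudioTrack", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate),
      responseIndex = as.integer(responseIndex))
}

#' @rdname AudioTrack
#' @param object,x An `AudioTrack`.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname AudioTrack
#' @export
setMethod("samples", "AudioTrack", function(x) x@samples)

#' @rdname AudioTrack
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname AudioTrack
#' @export
setMethod("sampleRate", "AudioTrack", function(x) x@sampleRate)

#' @rdname AudioTrack
#' @export
setGeneric("audioDuration", function(x) standardGeneric("audioDuration"))
#' @rdname AudioTrack
#' @export
setMethod("audioDuration", "AudioTrack",
          function(x) length(x@samples) / x@sampleRate)

setMethod("show", "AudioTrack", function(object) {
  cat(sprintf("AudioTrack: response %d, %.2f s @ %g Hz\n",
              object@responseIndex, audioDuration(object), object@sampleRate))
})

## ---------------------------------------------------------------------------
## LandmarkStream
## ---------------------------------------------------------------------------

#' @rdname LandmarkStream
#' @export
setClass("LandmarkStream",
  representation(timestamps = "numeric", landmarks = "array",
                 blendshapes = "matrix"))

setValidity("LandmarkStream", function(object) {
  msg <- character()
  n <- length(object@timestamps)
  d <- dim(object@landmarks)
  if (length(d) != 3L || d[1] != n || d[2] != landmarkCount() || d[3] != 3L) {
    msg <- c(msg, sprintf(
      "landmarks must be an n x %d x 3 array matching %d timestamps",
      landmarkCount(), n))
  }
  if (nrow(object@blendshapes) != n || ncol(object@blendshapes) != 52L) {
    msg <- c(msg, "blendshapes must be an n x 52 matrix")
  }
  if (!identical(colnames(object@blendshapes), blendshapeNames())) {
    msg <- c(msg, "blendshape columns must be the canonical 52 names, in order")
  }
  if (n > 1L && any(diff(object@timestamps) <= 0)) {
    msg <- c(msg, "timestamps must be strictly increasing")
  }
  if (n > 0L) {
    bs <- object@blendshapes
    if (min(bs) < -1e-9 || max(bs) > 1 + 1e-9) {
      msg <- c(msg, "blendshape scores must lie in [0, 1]")
    }
    xy <- object@landmarks[, , 1:2, drop = FALSE]
    if (min(xy) < -1e-9 || max(xy) > 1 + 1e-9) {
      msg <- c(msg, "landmark x and y must lie in [0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Timestamped facial landmark + blendshape stream
#'
#' Frames carry 478 landmark points in normalized image coordinates
#' (x rightward, y downward, origin top-left; z is relative depth and
#' unconstrained) and 52 named blendshape activations. Raw streams are
#' typically irregular at 30-60 fps; see [interpolateStream()].
#'
#' @param timestamps Numeric, strictly increasing, seconds from session start.
#' @param landmarks Numeric array `n x 478 x 3`.
#' @param blendshapes Numeric matrix `n x 52`; columns must be
#'   [blendshapeNames()] (they are reordered if named differently ordered).
#' @return A `LandmarkStream`.
#' @export
LandmarkStream <- function(timestamps, landmarks, blendshapes) {
  timestamps <- as.numeric(timestamps)
  if (!is.null(colnames(blendshapes)) &&
      !identical(colnames(blendshapes), blendshapeNames()) &&
      setequal(colnames(blendshapes), blendshapeNames())) {
    blendshapes <- blendshapes[, blendshapeNames(), drop = FALSE]
  }
  new("LandmarkStream", timestamps = timestamps,
      landmarks = landmarks, blendshapes = as.matrix(blendshapes))
}

#' @rdname LandmarkStream
#' @param x A `LandmarkStream`.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname LandmarkStream
#' @export
setMethod("frameTimes", "LandmarkStream", function(x) x@timestamps)

#' @rdname LandmarkStream
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname LandmarkStream
#' @export
setMethod("nFrames", "LandmarkStream", function(x) length(x@timestamps))

#' @rdname LandmarkStream
#' @export
setGeneric("blendshapes", function(x) standardGeneric("blendshapes"))
#' @rdname LandmarkStream
#' @export
setMethod("blendshapes", "LandmarkStream", function(x) x@blendshapes)

#' @rdname LandmarkStream
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))
#' @rdname LandmarkStream
#' @export
setMethod("landmarks", "LandmarkStream", function(x) x@landmarks)

setMethod("show", "LandmarkStream", function(object) {
  n <- nFrames(object)
  if (n) {
    span <- diff(range(object@timestamps))
    cat(sprintf("LandmarkStream: %d frames over %.2f s (~%.1f fps)\n",
                n, span, if (span > 0) (n - 1) / span else NA_real_))
  } else cat("LandmarkStream: empty\n")
})

## ---------------------------------------------------------------------------
## Transcript
## ---------------------------------------------------------------------------

#' @rdname Transcript
#' @export
setClass("Transcript",
  representation(turns = "data.frame", words = "data.frame"))

setValidity("Transcript", function(object) {
  msg <- character()
  tu <- object@turns
  need <- c("speaker", "text", "start", "end")
  if (!all(need %in% names(tu))) {
    msg <- c(msg, "turns must have columns speaker, text, start, end")
  } else {
    if (!all(tu$speaker %in% c("agent", "participant"))) {
      msg <- c(msg, "speaker must be 'agent' or 'participant'")
    }
    if (any(tu$start > tu$end)) msg <- c(msg, "turn start must be <= end")
  }
  wo <- object@words
  if (nrow(wo)) {
    needw <- c("turn", "token", "start", "end")
    if (!all(needw %in% names(wo))) {
      msg <- c(msg, "words must have columns turn, token, start, end")
    } else {
      for (ti in unique(wo$turn)) {
        w <- wo[wo$turn == ti, , drop = FALSE]
        if (ti < 1 || ti > nrow(tu)) {
          msg <- c(msg, sprintf("word timing refers to missing turn %d", ti))
          next
        }
        if (any(w$start < tu$start[ti] - 1e-6) ||
            any(w$end > tu$end[ti] + 1e-6)) {
          msg <- c(msg, sprintf("word timings outside turn %d span", ti))
        }
        w <- w[order(w$start), , drop = FALSE]
        if (nrow(w) > 1L && any(w$start[-1] < w$end[-nrow(w)] - 1e-6)) {
          msg <- c(msg, sprintf("overlapping word timings in turn %d", ti))
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Timed conversation transcript
#'
#' Ordered agent/participant turns with optional word-level timings. A
#' standard check-in has 5 agent turns and 4 participant responses,
#' alternating, agent first.
#'
#' @param turns data.frame with columns `speaker` ("agent"/"participant"),
#'   `text`, `start`, `end` (seconds).
#' @param words Optional data.frame with columns `turn` (row index into
#'   `turns`), `token`, `start`, `end`.
#' @return A `Transcript`.
#' @export
Transcript <- function(turns, words = NULL) {
  if (is.null(words)) {
    words <- data.frame(turn = integer(), token = character(),
                        start = numeric(), end = numeric(),
                        stringsAsFactors = FALSE)
  }
  new("Transcript", turns = as.data.frame(turns), words = as.data.frame(words))
}

#' @rdname Transcript
#' @param x A `Transcript`.
#' @export
setGeneric("turns", function(x) standardGeneric("turns"))
#' @rdname Transcript
#' @export
setMethod("turns", "Transcript", function(x) x@turns)

#' @rdname Transcript
#' @export
setGeneric("wordTimings", function(x) standardGeneric("wordTimings"))
#' @rdname Transcript
#' @export
setMethod("wordTimings", "Transcript", function(x) x@words)

#' @rdname Transcript
#' @export
setGeneric("participantTurns", function(x) standardGeneric("participantTurns"))
#' @rdname Transcript
#' @export
setMethod("participantTurns", "Transcript", function(x) {
  x@turns[x@turns$speaker == "participant", , drop = FALSE]
})

setMethod("show", "Transcript", function(object) {
  cat(sprintf("Transcript: %d turns (%d participant responses)\n",
              nrow(object@turns), sum(object@turns$speaker == "participant")))
})

## ---------------------------------------------------------------------------
## ClinicalScores
## ---------------------------------------------------------------------------

#' @rdname ClinicalScores
#' @export
setClass("ClinicalScores",
  representation(phq9Total = "numeric",
                 cfsPhysical = "numeric", cfsAffective = "numeric",
                 cfsCognitive = "numeric", cfsTotal = "numeric",
                 tmtASeconds = "numeric", tmtBSeconds = "numeric"))

setValidity("ClinicalScores", function(object) {
  msg <- character()
  if (object@phq9Total < 0 || object@phq9Total > 27) {
    msg <- c(msg, "phq9Total must lie in [0, 27]")
  }
  sub <- c(object@cfsPhysical, object@cfsAffective, object@cfsCognitive)
  if (any(sub < 0)) msg <- c(msg, "CFS subscales must be nonnegative")
  if (abs(object@cfsTotal - sum(sub)) > 1e-6) {
    msg <- c(msg, "cfsTotal must equal the sum of the three subscales")
  }
  if (object@tmtASeconds <= 0 || object@tmtBSeconds <= 0) {
    msg <- c(msg, "TMT completion times must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Clinical assessment scores for a session
#'
#' PHQ-9 depression total (0-27), Cancer Fatigue Scale subscales
#' (physical/affective/cognitive; total is their sum), and Trail Making
#' Test parts A and B completion times in seconds (longer = worse).
#'
#' @param phq9Total PHQ-9 total, 0-27.
#' @param cfsPhysical,cfsAffective,cfsCognitive CFS subscale scores.
#' @param tmtASeconds,tmtBSeconds TMT completion times, seconds, > 0.
#' @return A `ClinicalScores`.
#' @export
ClinicalScores <- function(phq9Total, cfsPhysical, cfsAffective, cfsCognitive,
                           tmtASeconds, tmtBSeconds) {
  new("ClinicalScores",
      phq9Total = as.numeric(phq9Total),
      cfsPhysical = as.numeric(cfsPhysical),
      cfsAffective = as.numeric(cfsAffective),
      cfsCognitive = as.numeric(cfsCognitive),
      cfsTotal = as.numeric(cfsPhysical + cfsAffective + cfsCognitive),
      tmtASeconds = as.numeric(tmtASeconds),
      tmtBSeconds = as.numeric(tmtBSeconds))
}

#' @rdname ClinicalScores
#' @param x A `ClinicalScores`.
#' @export
setGeneric("scoreVector", function(x) standardGeneric("scoreVector"))

#' @rdname ClinicalScores
#' @export
setMethod("scoreVector", "ClinicalScores", function(x) {
  c(phq9_total = x@phq9Total,
    cfs_total = x@cfsTotal, cfs_physical = x@cfsPhysical,
    cfs_affective = x@cfsAffective, cfs_cognitive = x@cfsCognitive,
    tmt_a_seconds = x@tmtASeconds, tmt_b_seconds = x@tmtBSeconds,
    tmt_total_seconds = x@tmtASeconds + x@tmtBSeconds)
})

setMethod("show", "ClinicalScores", function(object) {
  cat(sprintf("ClinicalScores: PHQ-9 %g, CFS %g (P %g / A %g / C %g), TMT %g+%g s\n",
              object@phq9Total, object@cfsTotal, object@cfsPhysical,
              object@cfsAffective, object@cfsCognitive,
              object@tmtASeconds, object@tmtBSeconds))
})

## ---------------------------------------------------------------------------
## CheckinSession
## ---------------------------------------------------------------------------

#' @rdname CheckinSession
#' @export
setClass("CheckinSession",
  representation(participantId = "character", sessionId = "character",
                 timestamp = "character",
                 landmarkStream = "LandmarkStream",
                 audioTracks = "list",
                 transcript = "Transcript",
                 clinicalScores = "ClinicalScores"))

setValidity("CheckinSession", function(object) {
  msg <- character()
  if (!all(vapply(object@audioTracks, is, TRUE, "AudioTrack"))) {
    msg <- c(msg, "audioTracks must all be AudioTrack objects")
  }
  np <- sum(object@transcript@turns$speaker == "participant")
  if (np != length(object@audioTracks)) {
    msg <- c(msg, sprintf(
      "number of participant turns (%d) must equal number of audio tracks (%d)",
      np, length(object@audioTracks)))
  }
  if (length(msg)) msg else TRUE
})

#' A complete check-in session
#'
#' Bundles one conversational session: the landmark/blendshape stream, one
#' audio track per participant response (default 4 responses per session),
#' the timed transcript, and the session's clinical scores.
#'
#' @param participantId,sessionId Identifier strings.
#' @param timestamp ISO-8601 session timestamp string.
#' @param landmarkStream A [LandmarkStream].
#' @param audioTracks List of [AudioTrack], one per participant response.
#' @param transcript A [Transcript].
#' @param clinicalScores A [ClinicalScores].
#' @return A `CheckinSession`.
#' @export
CheckinSession <- function(participantId, sessionId, timestamp,
                           landmarkStream, audioTracks, transcript,
                           clinicalScores) {
  new("CheckinSession", participantId = as.character(participantId),
      sessionId = as.character(sessionId), timestamp = as.character(timestamp),
      landmarkStream = landmarkStream, audioTracks = audioTracks,
      transcript = transcript, clinicalScores = clinicalScores)
}

#' @rdname CheckinSession
#' @param x A `CheckinSession`.
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))
#' @rdname CheckinSession
#' @export
setMethod("participantId", "CheckinSession", function(x) x@participantId)

#' @rdname CheckinSession
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @rdname CheckinSession
#' @export
setMethod("sessionId", "CheckinSession", function(x) x@sessionId)

#' @rdname CheckinSession
#' @export
setGeneric("sessionTimestamp", function(x) standardGeneric("sessionTimestamp"))
#' @rdname CheckinSession
#' @export
setMethod("sessionTimestamp", "CheckinSession", function(x) x@timestamp)

#' @rdname CheckinSession
#' @export
setGeneric("landmarkStream", function(x) standardGeneric("landmarkStream"))
#' @rdname CheckinSession
#' @export
setMethod("landmarkStream", "CheckinSession", function(x) x@landmarkStream)

#' @rdname CheckinSession
#' @export
setGeneric("audioTracks", function(x) standardGeneric("audioTracks"))
#' @rdname CheckinSession
#' @export
setMethod("audioTracks", "CheckinSession", function(x) x@audioTracks)

#' @rdname CheckinSession
#' @export
setGeneric("transcript", function(x) standardGeneric("transcript"))
#' @rdname CheckinSession
#' @export
setMethod("transcript", "CheckinSession", function(x) x@transcript)

#' @rdname CheckinSession
#' @export
setGeneric("clinicalScores", function(x) standardGeneric("clinicalScores"))
#' @rdname CheckinSession
#' @export
setMethod("clinicalScores", "CheckinSession", function(x) x@clinicalScores)

setMethod("show", "CheckinSession", function(object) {
  cat(sprintf("CheckinSession %s / %s (%s)\n", object@participantId,
              object@sessionId, object@timestamp))
  show(object@landmarkStream)
  cat(sprintf("  %d audio responses, ", length(object@audioTracks)))
  show(object@transcript)
})
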