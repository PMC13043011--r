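## Synthetic cohort generator: latent symptom severities per participant,
## session-level generator parameters coupled to the latents through a
## sign-controlled effect matrix, and full session synthesis (source-filter
## audio, blendshape streams, timed transcripts) plus a fast parameter-level
## feature table for statistical calibration studies.

#' Generator parameter table
#'
#' Baseline value, standardized unit (the parameter change corresponding to
#' one standard deviation of coupled latent), and the physically plausible
#' clipping range for every session-level generator parameter.
#'
#' @return data.frame with columns `param`, `base`, `unit`, `min`, `max`.
#' @export
paramDefaults <- function() {
  df <- rbind(
    data.frame(param = "f0_mean",        base = 140,  unit = 15,    min = 90,    max = 350),
    data.frame(param = "f0_slope",       base = 0,    unit = 3,     min = -20,   max = 20),
    data.frame(param = "rms_level",      base = 0.12, unit = 0.015, min = 0.03,  max = 0.3),
    data.frame(param = "rms_slope",      base = 0.005, unit = 0.004, min = -0.04, max = 0.04),
    data.frame(param = "rms_var",        base = 0.25, unit = 0.06,  min = 0.02,  max = 0.8),
    data.frame(param = "jitter_eps",     base = 0.01, unit = 0.004, min = 0.001, max = 0.06),
    data.frame(param = "shimmer_eps",    base = 0.06, unit = 0.02,  min = 0.005, max = 0.4),
    data.frame(param = "formant1",       base = 500,  unit = 30,    min = 320,   max = 900),
    data.frame(param = "formant2",       base = 1500, unit = 80,    min = 950,   max = 2400),
    data.frame(param = "formant3",       base = 2500, unit = 100,   min = 2000,  max = 3200),
    data.frame(param = "pause_rate",     base = 0.25, unit = 0.08,  min = 0,     max = 1),
    data.frame(param = "pause_len",      base = 0.45, unit = 0.1,   min = 0.3,   max = 1.5),
    data.frame(param = "blink_rate",     base = 0.25, unit = 0.06,  min = 0,     max = 1),
    data.frame(param = "yawn_rate",      base = 0.02, unit = 0.012, min = 0,     max = 0.2),
    data.frame(param = "droop",          base = 0.15, unit = 0.04,  min = 0,     max = 0.28),
    data.frame(param = "gaze_x",         base = 0,    unit = 0.05,  min = -0.4,  max = 0.4),
    data.frame(param = "gaze_down",      base = 0.1,  unit = 0.05,  min = 0,     max = 0.5),
    data.frame(param = "expr_var",       base = 0.05, unit = 0.015, min = 0.005, max = 0.2),
    data.frame(param = "filler_rate",    base = 0.1,  unit = 0.04,  min = 0,     max = 0.6),
    data.frame(param = "sentence_len",   base = 12,   unit = 2.5,   min = 4,     max = 25),
    data.frame(param = "long_word_prop", base = 0.15, unit = 0.05,  min = 0.02,  max = 0.5),
    data.frame(param = "sentiment",      base = 0,    unit = 0.3,   min = -1,    max = 1),
    data.frame(param = "latency",        base = 1.5,  unit = 0.4,   min = 0.2,   max = 5),
    data.frame(param = "speech_rate",    base = 2.5,  unit = 0.4,   min = 1,     max = 5))
  rownames(df) <- df$param
  df
}

#' Default latent-to-parameter effect matrix
#'
#' Standardized slopes from the three latent severities (depression,
#' fatigue, cognition) to generator parameters. Signs mirror the reported
#' feature-symptom directions: depression raises pitch and volume slope
#' and lowers volume variability and linguistic complexity; fatigue does
#' the same and additionally raises F2 and eyelid droop; cognitive
#' impairment (longer task completion) raises shimmer. Magnitudes are
#' calibration choices, not estimates.
#'
#' @param slope Magnitude used for every non-zero entry (default 0.5).
#' @return 3 x 24 numeric matrix, rows `depression`/`fatigue`/`cognition`,
#'   columns the parameters of [paramDefaults()].
#' @export
defaultEffects <- function(slope = 0.5) {
  pn <- paramDefaults()$param
  eff <- matrix(0, 3, length(pn),
                dimnames = list(c("depression", "fatigue", "cognition"), pn))
  eff["depression", c("f0_mean", "rms_slope")] <- slope
  eff["depression", c("rms_var", "sentence_len", "long_word_prop")] <- -slope
  eff["fatigue", c("f0_mean", "rms_slope", "formant2", "droop")] <- slope
  eff["fatigue", c("rms_var", "sentence_len", "long_word_prop")] <- -slope
  eff["cognition", "shimmer_eps"] <- slope
  eff
}

#' Cohort simulation configuration
#'
#' @param nParticipants Number of participants (>= 2).
#' @param sessionsPerParticipant Either a single integer or an integer
#'   vector of length `nParticipants`.
#' @param seed Integer seed; fixes the full output.
#' @param effects Effect matrix as from [defaultEffects()].
#' @param paramNoiseSd Session-level parameter noise, in standardized
#'   units (default 0.5).
#' @param measurementNoiseScale Fast-path measurement noise as a fraction
#'   of each feature's baseline magnitude (default 0.1).
#' @param latentCor Correlations among the latents: depression-fatigue,
#'   depression-cognition, fatigue-cognition.
#' @param ar1Rho,wanderSd Session-to-session AR(1) wander of the latents
#'   around each participant's base severity.
#' @param responseDur,agentDur Mean participant response and agent prompt
#'   durations in seconds (full synthesis).
#' @param paramTable Generator parameter table, normally
#'   [paramDefaults()]; baselines may be overridden, e.g. to synthesize
#'   shorter utterances.
#' @return A list of class `cohortConfig`.
#' @export
cohortConfig <- function(nParticipants = 8, sessionsPerParticipant = 3,
                         seed = 1, effects = defaultEffects(),
                         paramNoiseSd = 0.5, measurementNoiseScale = 0.1,
                         latentCor = c(0.5, 0.2, 0.2),
                         ar1Rho = 0.7, wanderSd = 0.3,
                         responseDur = 6, agentDur = 3,
                         paramTable = paramDefaults()) {
  stopifnot(nParticipants >= 2, all(is.finite(effects)))
  structure(list(
    nParticipants = as.integer(nParticipants),
    sessionsPerParticipant = sessionsPerParticipant,
    seed = as.integer(seed), effects = effects,
    paramNoiseSd = paramNoiseSd,
    measurementNoiseScale = measurementNoiseScale,
    latentCor = latentCor, ar1Rho = ar1Rho, wanderSd = wanderSd,
    responseDur = responseDur, agentDur = agentDur,
    paramTable = paramTable),
    class = "cohortConfig")
}

## correlated standard-normal latents per participant + AR(1) session wander
drawLatents <- function(config) {
  n <- config$nParticipants
  rho <- config$latentCor
  Sigma <- matrix(c(1, rho[1], rho[2],
                    rho[1], 1, rho[3],
                    rho[2], rho[3], 1), 3, 3)
  L <- chol(Sigma)
  base <- matrix(stats::rnorm(n * 3), n, 3) %*% L
  colnames(base) <- c("depression", "fatigue", "cognition")
  nSess <- config$sessionsPerParticipant
  if (length(nSess) == 1L) nSess <- rep(nSess, n)
  out <- NULL
  for (i in seq_len(n)) {
    w <- matrix(0, nSess[i], 3)
    for (s in seq_len(nSess[i])) {
      innov <- stats::rnorm(3, sd = config$wanderSd)
      w[s, ] <- if (s == 1L) innov else
        config$ar1Rho * w[s - 1L, ] + sqrt(1 - config$ar1Rho^2) * innov
    }
    lat <- sweep(w, 2, base[i, ], "+")
    out <- rbind(out, data.frame(
      participant = sprintf("P%02d", i), session = seq_len(nSess[i]),
      depression = lat[, 1], fatigue = lat[, 2], cognition = lat[, 3]))
  }
  out
}

## session latents -> clipped generator parameters
latentsToParams <- function(latents, config) {
  pd <- if (!is.null(config$paramTable)) config$paramTable else paramDefaults()
  eff <- config$effects[, pd$param, drop = FALSE]
  L <- as.matrix(latents[, c("depression", "fatigue", "cognition")])
  drive <- L %*% eff                       # sessions x params, in units
  noise <- matrix(stats::rnorm(length(drive), sd = config$paramNoiseSd),
                  nrow(drive), ncol(drive))
  raw <- sweep(sweep(drive + noise, 2, pd$unit, "*"), 2, pd$base, "+")
  clipped <- pmin(pmax(raw, matrix(pd$min, nrow(raw), ncol(raw),
                                   byrow = TRUE)),
                  matrix(pd$max, nrow(raw), ncol(raw), byrow = TRUE))
  nClip <- sum(raw != clipped)
  if (nClip > 0) {
    attr(clipped, "nClipped") <- nClip
  }
  colnames(clipped) <- pd$param
  clipped
}

## monotone latent -> instrument maps with noise, clipped to score ranges
latentsToScores <- function(latents) {
  n <- nrow(latents)
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  phys <- clip(round(14 + 5 * latents$fatigue + stats::rnorm(n, sd = 1.2)), 0, 28)
  aff <- clip(round(8 + 3 * latents$fatigue + stats::rnorm(n, sd = 1.0)), 0, 16)
  cog <- clip(round(8 + 2.5 * latents$fatigue + 1.0 * latents$cognition +
                      stats::rnorm(n, sd = 1.0)), 0, 16)
  tmtA <- exp(log(30) + 0.3 * latents$cognition + stats::rnorm(n, sd = 0.08))
  tmtB <- exp(log(70) + 0.3 * latents$cognition + stats::rnorm(n, sd = 0.08))
  data.frame(
    phq9_total = clip(round(9 + 5 * latents$depression +
                              stats::rnorm(n, sd = 1.5)), 0, 27),
    cfs_total = phys + aff + cog,
    cfs_physical = phys, cfs_affective = aff, cfs_cognitive = cog,
    tmt_a_seconds = tmtA, tmt_b_seconds = tmtB,
    tmt_total_seconds = tmtA + tmtB)
}

## deterministic expected feature values implied by a parameter vector;
## the couplings planted in parameters surface in their feature namesakes
paramsToExpectedFeatures <- function(p) {
  spw <- 1.3 + 1.8 * p["long_word_prop"]
  cw <- 3.8 + 4 * p["long_word_prop"]
  sl <- p["sentence_len"]
  c(affect_measure = unname(p["expr_var"]),
    mouth_curvature = unname(0.1 + 0.2 * p["sentiment"]),
    eyebrow_droop = unname(0.1 - 0.05 * p["sentiment"]),
    gaze_down_dist = unname(p["gaze_down"]),
    gaze_x_dist = unname(abs(p["gaze_x"]) + 0.02),
    gaze_y_dist = unname(p["gaze_down"] + 0.02),
    movement_speech_measure = unname(0.05 + 0.3 * p["expr_var"]),
    eyelid_droop = unname(p["droop"]),
    blinks_per_s = unname(p["blink_rate"]),
    blink_len = 0.15,
    yawns_per_s = unname(p["yawn_rate"]),
    yawn_len = 2.0,
    eye_movements_per_s = 0.5,
    pitch_mean = unname(p["f0_mean"]),
    pitch_std = unname(4 + 0.5 * abs(p["f0_slope"])),
    pitch_range = unname(12 + 1.5 * abs(p["f0_slope"])),
    pitch_slope = unname(p["f0_slope"]),
    vol_mean = unname(p["rms_level"]),
    vol_std = unname(p["rms_level"] * p["rms_var"] / sqrt(2)),
    vol_range = unname(2.2 * p["rms_level"] * p["rms_var"]),
    vol_slope = unname(p["rms_slope"]),
    ealvi = unname(0.05 + 0.25 * p["rms_var"]),
    jitter_local = unname(0.8 * p["jitter_eps"]),
    jitter_rap = unname(0.5 * p["jitter_eps"]),
    shimmer_local = unname(0.8 * p["shimmer_eps"]),
    shimmer_db = unname(7 * p["shimmer_eps"]),
    hnr_mean = unname(25 - 150 * p["jitter_eps"]),
    spectral_centroid_mean = unname(400 + 0.4 * p["formant2"]),
    spectral_centroid_std = 120,
    spectral_bandwidth_mean = unname(600 + 0.2 * p["formant2"]),
    spectral_flatness_mean = unname(0.05 + 0.5 * p["jitter_eps"]),
    spectral_rolloff_mean = unname(1500 + 0.6 * p["formant2"]),
    f1_mean = unname(p["formant1"]),
    f2_mean = unname(p["formant2"]),
    f3_mean = unname(p["formant3"]),
    f1_std = 30, f2_std = 60,
    f2_f1_ratio = unname(p["formant2"] / p["formant1"]),
    pause_rate = unname(p["pause_rate"]),
    pause_mean_len = unname(p["pause_len"]),
    voiced_fraction = unname(0.75 - 0.25 * p["pause_rate"] * p["pause_len"]),
    words_per_s = unname(p["speech_rate"]),
    response_latency_mean = unname(p["latency"]),
    response_latency_std = 0.25,
    transcript_len_words = unname(8 * sl),
    mean_response_len_words = unname(2 * sl),
    ari_complexity = unname(4.71 * cw + 0.5 * sl - 21.43),
    fk_complexity = unname(0.39 * sl + 11.8 * spw - 15.59),
    gunning_fog_complexity = unname(0.4 * (sl + 100 * p["long_word_prop"])),
    sentiment_mean = unname(0.15 * p["sentiment"]),
    sentiment_std = 0.05,
    emotion_keyword_prop = unname(0.04 + 0.04 * abs(p["sentiment"])),
    positive_emotion_prop = unname(0.02 + 0.04 * pmax(p["sentiment"], 0)),
    negative_emotion_prop = unname(0.02 + 0.04 * pmax(-p["sentiment"], 0)),
    hesitations_per_s = unname(p["filler_rate"]),
    hesitation_prop = unname(p["filler_rate"] / p["speech_rate"]),
    transcript_pause_rate = unname(p["pause_rate"]),
    transcript_pause_mean_len = unname(p["pause_len"] + 0.2),
    type_token_ratio = unname(pmin(1, 0.85 - 0.008 * sl)),
    mean_word_len = unname(cw),
    mean_sentence_len = unname(sl),
    first_person_singular_prop = 0.1,
    negation_prop = unname(pmax(0, 0.03 - 0.02 * p["sentiment"])),
    content_word_prop = unname(0.45 + 0.2 * p["long_word_prop"]),
    syllables_per_word = unname(spw),
    long_word_prop = unname(p["long_word_prop"]))
}

#' Simulate a cohort feature table (parameter-level fast path)
#'
#' Draws per-participant latent severities and per-session generator
#' parameters exactly as [simulateCohort()] does, then maps parameters
#' directly to their expected feature values (plus measurement noise)
#' instead of synthesizing and re-analyzing raw audio/landmark streams.
#' The extraction round trip that justifies this shortcut (parameters ->
#' raw session -> extracted features) is validated separately at small
#' scale; the fast path is what makes 100-replicate calibration and power
#' studies tractable.
#'
#' @param config A [cohortConfig()].
#' @param latents Optional data.frame overriding the generated latent
#'   trajectories (columns `participant`, `session`, `depression`,
#'   `fatigue`, `cognition`).
#' @return List with `se` (cohort `SummarizedExperiment`) and `truth`
#'   (latents and generator parameters per session).
#' @export
simulateFeatureTable <- function(config = cohortConfig(), latents = NULL) {
  set.seed(config$seed)
  if (is.null(latents)) latents <- drawLatents(config)
  params <- latentsToParams(latents, config)
  scores <- latentsToScores(latents)

  expected <- t(apply(params, 1, paramsToExpectedFeatures))
  colnames(expected) <- featureNames66()
  scale <- pmax(abs(colMeans(expected)), 0.01)
  noise <- sweep(matrix(stats::rnorm(length(expected)),
                        nrow(expected), ncol(expected)),
                 2, config$measurementNoiseScale * scale, "*")
  mat <- t(expected + noise)

  info <- data.frame(
    participant_id = latents$participant,
    session_id = sprintf("%s_S%02d", latents$participant, latents$session),
    timestamp = format(as.POSIXct("2025-03-06 09:00:00", tz = "UTC") +
                         86400 * (latents$session - 1) +
                         3600 * as.integer(factor(latents$participant)),
                       "%Y-%m-%dT%H:%M:%SZ"),
    scores, stringsAsFactors = FALSE)
  rownames(mat) <- featureNames66()
  list(se = makeCohortSE(mat, info),
       truth = cbind(latents, as.data.frame(params)))
}

## ---------------------------------------------------------------------------
## Full synthesis: audio, landmarks, transcript
## ---------------------------------------------------------------------------

#' Synthesize one response's audio from generator parameters
#'
#' Source-filter synthesis: a glottal impulse train with per-cycle period
#' perturbation (`jitter_eps`) and amplitude perturbation (`shimmer_eps`),
#' a linear f0 trajectory (`f0_mean`, `f0_slope`, centered mid-response),
#' filtered through three resonators at the formant targets. The carrier
#' is normalized to unit RMS and shaped by the programmed RMS envelope
#' (`rms_level` + `rms_slope` (t - dur/2), with sinusoidal modulation of
#' relative depth `rms_var`), and silences are inserted per the pause
#' parameters. Impulses are placed with fractional-sample linear splitting
#' so programmed jitter is not floored by sample quantization.
#'
#' @param params Named numeric vector of generator parameters (see
#'   [paramDefaults()]).
#' @param duration Response duration in seconds.
#' @param sampleRate Sampling rate in Hz (default 22050).
#' @param responseIndex 1-based response number.
#' @param returnCycles Also return the realized glottal-cycle onset times
#'   and amplitudes (the ground truth for perturbation oracles).
#' @return An [AudioTrack]; with `returnCycles = TRUE`, a list with
#'   elements `track`, `cycleTimes`, `cycleAmps`.
#' @export
synthAudio <- function(params, duration = 6, sampleRate = 22050,
                       responseIndex = 1L, returnCycles = FALSE) {
  p <- params; sr <- sampleRate
  n <- round(duration * sr)
  x <- numeric(n + 1L)
  t <- 0
  cycleTimes <- numeric(0); cycleAmps <- numeric(0)
  while (t < duration) {
    f0 <- p["f0_mean"] + p["f0_slope"] * (t - duration / 2)
    f0 <- max(60, f0)
    period <- (1 / f0) * (1 + p["jitter_eps"] * stats::rnorm(1))
    amp <- 1 + p["shimmer_eps"] * stats::rnorm(1)
    pos <- t * sr + 1
    k <- floor(pos); frac <- pos - k
    if (k >= 1 && k <= n) {
      x[k] <- x[k] + amp * (1 - frac)
      x[k + 1L] <- x[k + 1L] + amp * frac
      cycleTimes <- c(cycleTimes, t); cycleAmps <- c(cycleAmps, amp)
    }
    t <- t + period
  }
  x <- x[seq_len(n)]
  bw <- c(80, 110, 140)
  fs <- c(p["formant1"], p["formant2"], p["formant3"])
  for (i in 1:3) {
    r <- exp(-pi * bw[i] / sr)
    th <- 2 * pi * fs[i] / sr
    x <- as.numeric(stats::filter(x, c(2 * r * cos(th), -r^2),
                                  method = "recursive"))
  }
  x <- x / sqrt(mean(x^2))

  tt <- (seq_len(n) - 0.5) / sr
  env <- p["rms_level"] + p["rms_slope"] * (tt - duration / 2)
  env <- pmax(env, 0.01)
  mod <- 1 + p["rms_var"] * sin(2 * pi * 0.4 * tt + stats::runif(1, 0, 2 * pi))
  x <- x * env * pmax(mod, 0)

  ## insert silences (pauses) away from the edges
  nPause <- stats::rpois(1, p["pause_rate"] * duration)
  if (nPause > 0) {
    for (ps in stats::runif(nPause, 0.1 * duration, 0.9 * duration)) {
      i0 <- max(1L, round(ps * sr))
      i1 <- min(n, round((ps + p["pause_len"]) * sr))
      x[i0:i1] <- 0
      ramp <- round(0.01 * sr)
      lo <- max(1L, i0 - ramp); hi <- min(n, i1 + ramp)
      if (i0 > lo) x[lo:i0] <- x[lo:i0] * seq(1, 0, length.out = i0 - lo + 1L)
      if (hi > i1) x[i1:hi] <- x[i1:hi] * seq(0, 1, length.out = hi - i1 + 1L)
    }
  }
  peak <- max(abs(x))
  if (peak > 0.99) x <- x * 0.99 / peak
  track <- AudioTrack(x, sr, responseIndex)
  if (returnCycles) {
    list(track = track, cycleTimes = cycleTimes, cycleAmps = cycleAmps)
  } else track
}

## smooth random wiggle in [0, 1]-safe units: AR(1)-filtered gaussian noise
smoothNoise <- function(n, sd, rho = 0.97) {
  z <- stats::rnorm(n, sd = sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(z, rho, method = "recursive"))
}

#' Synthesize a landmark/blendshape stream
#'
#' Irregular timestamps with instantaneous rate uniform in 30-60 fps;
#' blink and yawn events as Poisson processes driving the eye-blink and
#' `jawOpen` blendshapes on top of the programmed eyelid droop baseline;
#' gaze offsets with occasional saccades; expression blendshapes wander
#' with the programmed variability; landmarks ride a small smooth head
#' motion, larger during speech segments.
#'
#' @inheritParams synthAudio
#' @param duration Stream duration in seconds.
#' @param speechSegments Optional data.frame (`start`, `end`) of
#'   participant-speaking intervals.
#' @return A [LandmarkStream].
#' @export
synthLandmarks <- function(params, duration, speechSegments = NULL) {
  p <- params
  tt <- numeric(0)
  t <- 0
  while (t <= duration) {
    tt <- c(tt, t)
    t <- t + 1 / stats::runif(1, 30, 60)
  }
  n <- length(tt)
  bs <- matrix(0, n, 52L, dimnames = list(NULL, blendshapeNames()))

  inSpeech <- rep(FALSE, n)
  if (!is.null(speechSegments)) {
    for (i in seq_len(nrow(speechSegments))) {
      inSpeech[tt >= speechSegments$start[i] &
               tt <= speechSegments$end[i]] <- TRUE
    }
  }

  ## eyelid: droop baseline + blink pulses (~150 ms, amplitude 0.9)
  lid <- rep(p["droop"], n)
  nBlink <- stats::rpois(1, p["blink_rate"] * duration)
  for (b in stats::runif(nBlink, 0, max(0, duration - 0.2))) {
    lid[tt >= b & tt < b + 0.15] <- 0.9
  }
  bs[, "eyeBlinkLeft"] <- bs[, "eyeBlinkRight"] <- lid

  ## jaw: yawn events (~2 s, amplitude 0.8) + speech articulation wiggle
  jaw <- ifelse(inSpeech, 0.15 + 0.15 * abs(sin(2 * pi * 2.5 * tt)), 0.02)
  nYawn <- stats::rpois(1, p["yawn_rate"] * duration)
  for (y in stats::runif(nYawn, 0, max(0, duration - 2.2))) {
    jaw[tt >= y & tt < y + 2.0] <- 0.8
  }
  bs[, "jawOpen"] <- jaw

  ## gaze: programmed offsets + drift + occasional saccades
  gx <- p["gaze_x"] + smoothNoise(n, 0.02)
  gy <- p["gaze_down"] + smoothNoise(n, 0.02)
  nSacc <- stats::rpois(1, 0.5 * duration)
  for (s in stats::runif(nSacc, 0, duration)) {
    hit <- tt >= s & tt < s + 0.1
    gx[hit] <- gx[hit] + stats::runif(1, -0.3, 0.3)
    gy[hit] <- gy[hit] + stats::runif(1, -0.2, 0.2)
  }
  clip01 <- function(v) pmin(1, pmax(0, v))
  bs[, "eyeLookInLeft"] <- bs[, "eyeLookOutRight"] <- clip01(gx)
  bs[, "eyeLookOutLeft"] <- bs[, "eyeLookInRight"] <- clip01(-gx)
  bs[, "eyeLookDownLeft"] <- bs[, "eyeLookDownRight"] <- clip01(gy)
  bs[, "eyeLookUpLeft"] <- bs[, "eyeLookUpRight"] <- clip01(-gy)

  ## expression channels wander with the programmed variability
  exprCh <- c("mouthSmileLeft", "mouthSmileRight", "mouthFrownLeft",
              "mouthFrownRight", "browDownLeft", "browDownRight",
              "browInnerUp", "cheekSquintLeft", "cheekSquintRight",
              "mouthPressLeft", "mouthPressRight", "noseSneerLeft")
  baseAct <- c(0.2 + 0.15 * max(0, p["sentiment"]),
               0.2 + 0.15 * max(0, p["sentiment"]),
               0.1 + 0.15 * max(0, -p["sentiment"]),
               0.1 + 0.15 * max(0, -p["sentiment"]),
               0.15, 0.15, 0.1, 0.1, 0.1, 0.1, 0.1, 0.05)
  for (k in seq_along(exprCh)) {
    bs[, exprCh[k]] <- clip01(baseAct[k] + smoothNoise(n, p["expr_var"]))
  }
  bs[] <- clip01(bs)

  ## landmarks: fixed face layout + smooth head motion (larger in speech)
  i <- seq_len(landmarkCount())
  baseX <- 0.35 + 0.3 * ((i - 1) %% 22) / 21
  baseY <- 0.25 + 0.45 * ((i - 1) %/% 22) / 21
  baseZ <- 0.02 * sin(i / 7)
  driftX <- smoothNoise(n, 0.004) + ifelse(inSpeech, smoothNoise(n, 0.006), 0)
  driftY <- smoothNoise(n, 0.004) + ifelse(inSpeech, smoothNoise(n, 0.006), 0)
  lm <- array(0, dim = c(n, landmarkCount(), 3L))
  lm[, , 1] <- clip01(outer(driftX, baseX, "+"))
  lm[, , 2] <- clip01(outer(driftY, baseY, "+"))
  lm[, , 3] <- outer(rep(0, n), baseZ, "+")
  LandmarkStream(tt, lm, bs)
}

## small word banks for transcript assembly (syllable counts per the
## package's own counter, so programmed long-word proportions are exact)
wordBankMono <- function() {
  c("day", "work", "time", "sleep", "week", "home", "team", "plan", "walk",
    "run", "food", "rest", "task", "shift", "night", "friend", "talk",
    "thing", "place", "point", "goal", "house", "road", "drive", "train",
    "book", "call", "mind", "mood", "life", "job", "group", "part", "start",
    "end", "way", "step", "phase", "note", "form")
}
wordBankLong <- function() {
  c("generally", "probably", "everything", "responsibility", "opportunity",
    "understanding", "energetic", "difficulty", "immediately", "absolutely",
    "definitely", "organization", "conversation", "situation", "activity",
    "exercises", "memory", "attention", "family", "evaluation",
    "performance", "occasionally", "communication", "operation")
}

#' Synthesize a timed transcript
#'
#' Five agent prompts and four participant responses, alternating, agent
#' first. Participant text is assembled from word banks to hit the
#' programmed filler rate, sentence length, long-word proportion and
#' sentiment valence; word timings follow the programmed speech rate and
#' response latency.
#'
#' @inheritParams synthAudio
#' @param nResponses Number of participant responses (default 4).
#' @return List with `transcript` (a [Transcript]) and `responseDurations`
#'   (seconds per participant response).
#' @export
synthTranscript <- function(params, nResponses = 4L) {
  p <- params
  lex <- loadLexicons()
  agentPrompts <- c(
    "Hello, how are you feeling today?",
    "Thanks for sharing. What has your energy been like this week?",
    "I see. How has your sleep been recently?",
    "Understood. Is there anything on your mind you want to talk about?",
    "Thank you for checking in today. Take care.")
  turnsList <- list(); wordsList <- list()
  tcur <- 0
  agentDur <- 3
  respDur <- numeric(nResponses)
  for (k in seq_len(nResponses + 1L)) {
    turnsList[[length(turnsList) + 1L]] <- data.frame(
      speaker = "agent", text = agentPrompts[k],
      start = tcur, end = tcur + agentDur, stringsAsFactors = FALSE)
    tcur <- tcur + agentDur
    if (k > nResponses) break

    nWords <- max(6L, round(2 * p["sentence_len"]))
    nLong <- round(p["long_word_prop"] * nWords)
    nFill <- stats::rpois(1, p["filler_rate"] * nWords / p["speech_rate"])
    nEmo <- min(nWords %/% 5L, stats::rpois(1, 1 + 2 * abs(p["sentiment"])))
    emoBank <- if (p["sentiment"] >= 0) lex$positive else lex$negative
    nPlain <- max(0L, nWords - nLong - nFill - nEmo)
    toks <- c(sample(wordBankLong(), nLong, replace = TRUE),
              sample(defaultConfig()$text$fillers, nFill, replace = TRUE),
              sample(emoBank, nEmo, replace = TRUE),
              sample(wordBankMono(), nPlain, replace = TRUE))
    toks <- sample(toks)
    nSent <- max(1L, round(length(toks) / p["sentence_len"]))
    bounds <- unique(round(seq(0, length(toks), length.out = nSent + 1L)))
    sentences <- vapply(seq_len(length(bounds) - 1L), function(s) {
      paste(toks[(bounds[s] + 1L):bounds[s + 1L]], collapse = " ")
    }, character(1))
    text <- paste0(paste(sentences, collapse = ". "), ".")

    start <- tcur + max(0.2, p["latency"])
    wdur <- 0.8 / p["speech_rate"]; wgap <- 0.2 / p["speech_rate"]
    wstart <- start + (seq_along(toks) - 1L) * (wdur + wgap)
    wend <- wstart + wdur
    end <- wend[length(wend)]
    turnsList[[length(turnsList) + 1L]] <- data.frame(
      speaker = "participant", text = text,
      start = start, end = end, stringsAsFactors = FALSE)
    wordsList[[length(wordsList) + 1L]] <- data.frame(
      turn = length(turnsList), token = toks,
      start = wstart, end = wend, stringsAsFactors = FALSE)
    respDur[k] <- end - start
    tcur <- end + 0.3
  }
  tu <- do.call(rbind, turnsList)
  wo <- do.call(rbind, wordsList)
  list(transcript = Transcript(tu, wo), responseDurations = respDur)
}

#' Simulate a full synthetic cohort of session bundles
#'
#' Per participant, latent severities are drawn once (with AR(1)
#' session-to-session wander); per session, generator parameters are
#' `baseline + effects x latents + noise` (clipped to plausible ranges),
#' and a complete [CheckinSession] is synthesized: timed transcript,
#' source-filter audio per response, and the landmark/blendshape stream
#' spanning the conversation. Clinical scores are monotone maps of the
#' latents with noise, clipped to instrument ranges.
#'
#' @param config A [cohortConfig()].
#' @param outDir Optional directory: each session is also written as a
#'   standard bundle (see [writeSession()]) plus `cohort_truth.json` with
#'   all latents and parameters.
#' @param latents Optional latent-trajectory override as in
#'   [simulateFeatureTable()].
#' @return List with `sessions` (list of [CheckinSession]) and `truth`.
#' @export
simulateCohort <- function(config = cohortConfig(), outDir = NULL,
                           latents = NULL) {
  set.seed(config$seed)
  if (is.null(latents)) latents <- drawLatents(config)
  params <- latentsToParams(latents, config)
  scores <- latentsToScores(latents)

  sessions <- vector("list", nrow(latents))
  for (s in seq_len(nrow(latents))) {
    p <- params[s, ]
    tx <- synthTranscript(p)
    pt <- participantTurns(tx$transcript)
    tracks <- lapply(seq_len(nrow(pt)), function(k) {
      synthAudio(p, duration = max(1.5, tx$responseDurations[k]),
                 responseIndex = k)
    })
    segs <- data.frame(start = pt$start, end = pt$end)
    stream <- synthLandmarks(p, duration = max(turns(tx$transcript)$end),
                             speechSegments = segs)
    cs <- ClinicalScores(scores$phq9_total[s], scores$cfs_physical[s],
                         scores$cfs_affective[s], scores$cfs_cognitive[s],
                         scores$tmt_a_seconds[s], scores$tmt_b_seconds[s])
    ts <- format(as.POSIXct("2025-03-06 09:00:00", tz = "UTC") +
                   86400 * (latents$session[s] - 1) +
                   3600 * as.integer(factor(latents$participant))[s],
                 "%Y-%m-%dT%H:%M:%SZ")
    sessions[[s]] <- CheckinSession(
      latents$participant[s],
      sprintf("%s_S%02d", latents$participant[s], latents$session[s]),
      ts, stream, tracks, tx$transcript, cs)
  }
  truth <- cbind(latents, as.data.frame(params))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (s in sessions) writeSession(s, file.path(outDir, sessionId(s)))
    jsonlite::write_json(truth, file.path(outDir, "cohort_truth.json"),
                         dataframe = "rows", digits = NA)
  }
  list(sessions = sessions, truth = truth)
}
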