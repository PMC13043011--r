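## Acoustic features from resampled mono responses: volume envelope, f0
## tracking, perturbation (jitter/shimmer/HNR), short-time spectral
## descriptors, LPC formants, and pause statistics. 28 features total.

## short-time framing + per-frame RMS, normalized autocorrelation pitch,
## and power spectra; the single pass shared by all acoustic ops
acousticFrames <- function(x, sr, cfg = defaultConfig()$audio) {
  fl <- cfg$frame_length; hop <- cfg$hop_length
  if (length(x) < fl) x <- c(x, rep(0, fl - length(x)))
  starts <- seq(1L, length(x) - fl + 1L, by = hop)
  n <- length(starts)
  fr <- matrix(0, fl, n)
  for (j in seq_len(n)) fr[, j] <- x[starts[j]:(starts[j] + fl - 1L)]
  times <- (starts - 1L + fl / 2) / sr
  rms <- sqrt(colMeans(fr^2))
  thr <- max(rms) * 10^(cfg$silence_db / 20)
  speech <- rms > thr & max(rms) > 1e-8

  ## normalized ACF via FFT on mean-removed frames
  frc <- sweep(fr, 2, colMeans(fr))
  nfft <- 2L * fl
  Fm <- stats::mvfft(rbind(frc, matrix(0, nfft - fl, n)))
  ac <- Re(stats::mvfft(Fm * Conj(Fm), inverse = TRUE)) / nfft
  lagMin <- max(2L, floor(sr / cfg$f_max))
  lagMax <- min(fl - 2L, ceiling(sr / cfg$f_min))
  f0 <- rep(NA_real_, n)
  strength <- rep(0, n)
  for (j in seq_len(n)) {
    a0 <- ac[1L, j]
    if (a0 <= 1e-12) next
    seg <- ac[(lagMin + 1L):(lagMax + 1L), j] / a0
    k <- which.max(seg)
    lag <- lagMin + k - 1L
    ## parabolic interpolation for sub-sample period
    if (k > 1L && k < length(seg)) {
      y1 <- seg[k - 1L]; y2 <- seg[k]; y3 <- seg[k + 1L]
      den <- y1 - 2 * y2 + y3
      d <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
      d <- max(-0.5, min(0.5, d))
      lag <- lag + d
      strength[j] <- y2 - 0.25 * (y1 - y3) * d
    } else strength[j] <- seg[k]
    f0[j] <- sr / lag
  }
  voiced <- speech & strength > cfg$voicing_threshold & !is.na(f0)
  f0[!voiced] <- NA_real_

  ## power spectra (hann window) for the spectral descriptors
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(fl) / (fl + 1))
  Fw <- stats::mvfft(fr * win)
  nb <- fl %/% 2L
  pow <- abs(Fw[2:(nb + 1L), , drop = FALSE])^2   # skip DC
  freqs <- (1:nb) * sr / fl

  list(times = times, rms = rms, speech = speech, f0 = f0,
       strength = strength, voiced = voiced, pow = pow, freqs = freqs,
       sr = sr, frameLength = fl, hop = hop, starts = starts,
       duration = length(x) / sr)
}

olsSlope <- function(t, y) {
  if (length(t) < 2L || stats::sd(t) == 0) return(NA_real_)
  stats::cov(t, y) / stats::var(t)
}

#' Frame RMS volume envelope and volume features
#'
#' Frame RMS with the configured window/hop. `vol_mean`, `vol_std` and
#' `vol_range` are computed over speech frames (frames above the silence
#' threshold); `vol_slope` is the least-squares slope of speech-frame RMS
#' against time over the response, in RMS units per second. A silent track
#' yields all-`NA` volume features.
#'
#' @param track A resampled [AudioTrack].
#' @param config Configuration list, see [defaultConfig()].
#' @return List with the frame series (`times`, `rms`, `speech`) and
#'   `features`, a named numeric vector
#'   (`vol_mean`, `vol_std`, `vol_range`, `vol_slope`, `ealvi`).
#' @export
volumeEnvelope <- function(track, config = defaultConfig()) {
  af <- acousticFrames(samples(track), sampleRate(track), config$audio)
  sp <- af$speech
  feats <- c(vol_mean = NA_real_, vol_std = NA_real_, vol_range = NA_real_,
             vol_slope = NA_real_, ealvi = NA_real_)
  if (any(sp)) {
    r <- af$rms[sp]
    feats["vol_mean"] <- mean(r)
    feats["vol_std"] <- if (length(r) > 1L) stats::sd(r) else 0
    feats["vol_range"] <- diff(range(r))
    feats["vol_slope"] <- olsSlope(af$times[sp], r)
    feats["ealvi"] <- ealvi(r)
  }
  list(times = af$times, rms = af$rms, speech = af$speech, features = feats)
}

#' Energy-adjusted low-volume index (ealvi)
#'
#' Fraction of speech frames whose RMS falls below half the response's
#' median speech-frame RMS. This realizes the low-volume index as a
#' declared, deterministic substitute definition (the production
#' definition is not published); treat values as internally comparable
#' only.
#'
#' @param speechRms Numeric vector of speech-frame RMS values.
#' @return Scalar in \[0, 1\], or `NA` for an empty input.
#' @export
ealvi <- function(speechRms) {
  speechRms <- speechRms[!is.na(speechRms)]
  if (!length(speechRms)) return(NA_real_)
  mean(speechRms < 0.5 * stats::median(speechRms))
}

#' Fundamental-frequency track and pitch features
#'
#' Normalized-autocorrelation f0 estimation per frame within the configured
#' search range (default 75-500 Hz) with parabolic peak interpolation;
#' frames are voiced when above the silence threshold and the periodicity
#' strength exceeds the voicing threshold. Pitch statistics are computed
#' over voiced frames; `voiced_fraction` is voiced frames / total frames.
#'
#' @inheritParams volumeEnvelope
#' @return List with the frame series (`times`, `f0`, `voiced`) and
#'   `features` (`pitch_mean`, `pitch_std`, `pitch_range`, `pitch_slope`,
#'   `voiced_fraction`).
#' @export
pitchTrack <- function(track, config = defaultConfig()) {
  af <- acousticFrames(samples(track), sampleRate(track), config$audio)
  vo <- af$voiced
  feats <- c(pitch_mean = NA_real_, pitch_std = NA_real_,
             pitch_range = NA_real_, pitch_slope = NA_real_,
             voiced_fraction = mean(vo))
  if (any(vo)) {
    f <- af$f0[vo]
    feats["pitch_mean"] <- mean(f)
    feats["pitch_std"] <- if (length(f) > 1L) stats::sd(f) else 0
    feats["pitch_range"] <- diff(range(f))
    feats["pitch_slope"] <- olsSlope(af$times[vo], f)
  }
  list(times = af$times, f0 = af$f0, voiced = af$voiced, features = feats)
}

## glottal-cycle marking by period-guided peak picking with parabolic
## refinement; returns peak times (s) and amplitudes
cycleMarks <- function(x, sr, f0) {
  T0 <- sr / f0                      # period in samples
  n <- length(x)
  if (n < 3 * T0) return(NULL)
  ## first marker: maximum within the first two periods
  i <- which.max(x[1:min(n, ceiling(2 * T0))])
  times <- numeric(0); amps <- numeric(0)
  Tloc <- T0
  while (i + 0.6 * Tloc < n) {
    lo <- max(1L, floor(i + 0.6 * Tloc))
    hi <- min(n, ceiling(i + 1.4 * Tloc))
    if (hi - lo < 2L) break
    j <- lo - 1L + which.max(x[lo:hi])
    ## parabolic refinement of location and amplitude
    tRef <- j; aRef <- x[j]
    if (j > 1L && j < n) {
      y1 <- x[j - 1L]; y2 <- x[j]; y3 <- x[j + 1L]
      den <- y1 - 2 * y2 + y3
      if (abs(den) > 1e-12) {
        d <- 0.5 * (y1 - y3) / den
        d <- max(-0.5, min(0.5, d))
        tRef <- j + d
        aRef <- y2 - 0.25 * (y1 - y3) * d
      }
    }
    if (length(times)) Tloc <- tRef - times[length(times)] * sr
    times <- c(times, tRef / sr)
    amps <- c(amps, aRef)
    i <- tRef
    if (Tloc < 2 || Tloc > 4 * T0) break
  }
  if (length(times) < 3L) return(NULL)
  list(times = times, amps = amps)
}

#' Jitter, shimmer and harmonics-to-noise ratio
#'
#' Glottal cycles are marked by period-guided peak picking (seeded by the
#' median f0 of the voiced frames, refined by parabolic interpolation) over
#' the longest contiguous speech stretch. Jitter is the mean absolute
#' consecutive-period difference over the mean period (`jitter_local`) and
#' its 3-period relative-average-perturbation variant (`jitter_rap`);
#' shimmer is the analogous cycle-amplitude perturbation, relative
#' (`shimmer_local`) and in dB (`shimmer_db`). `hnr_mean` is the mean
#' autocorrelation harmonicity of voiced frames, `10 log10(r / (1 - r))`,
#' capped at 40 dB. Fewer than 3 detected cycles yields `NA`s.
#'
#' @inheritParams volumeEnvelope
#' @return Named numeric vector (`jitter_local`, `jitter_rap`,
#'   `shimmer_local`, `shimmer_db`, `hnr_mean`).
#' @export
perturbationFeatures <- function(track, config = defaultConfig()) {
  out <- c(jitter_local = NA_real_, jitter_rap = NA_real_,
           shimmer_local = NA_real_, shimmer_db = NA_real_,
           hnr_mean = NA_real_)
  af <- acousticFrames(samples(track), sampleRate(track), config$audio)
  if (!any(af$voiced)) return(out)
  r <- pmin(af$strength[af$voiced], 1 - 1e-4)
  r <- pmax(r, 1e-4)
  out["hnr_mean"] <- mean(10 * log10(r / (1 - r)))

  f0med <- stats::median(af$f0[af$voiced])
  ## longest contiguous voiced stretch, in samples
  run <- rle(af$voiced)
  ends <- cumsum(run$lengths)
  vi <- which(run$values)
  if (!length(vi)) return(out)
  best <- vi[which.max(run$lengths[vi])]
  frLo <- ends[best] - run$lengths[best] + 1L
  frHi <- ends[best]
  sLo <- af$starts[frLo]
  sHi <- min(length(samples(track)), af$starts[frHi] + af$frameLength - 1L)
  cm <- cycleMarks(samples(track)[sLo:sHi], sampleRate(track), f0med)
  if (is.null(cm)) return(out)
  p <- diff(cm$times)
  keep <- abs(p - stats::median(p)) < 0.3 * stats::median(p)
  p <- p[keep]
  a <- cm$amps[-1][keep]
  a <- a[a > 0]
  if (length(p) >= 3L) {
    out["jitter_local"] <- mean(abs(diff(p))) / mean(p)
    if (length(p) >= 3L) {
      rap <- vapply(2:(length(p) - 1L), function(i) {
        abs(p[i] - mean(p[(i - 1L):(i + 1L)]))
      }, numeric(1))
      out["jitter_rap"] <- mean(rap) / mean(p)
    }
  }
  if (length(a) >= 3L) {
    out["shimmer_local"] <- mean(abs(diff(a))) / mean(a)
    out["shimmer_db"] <- mean(abs(20 * log10(a[-1] / a[-length(a)])))
  }
  out
}

#' Short-time spectral descriptors
#'
#' Standard spectral shape statistics on the hann-windowed power spectrum,
#' averaged over speech frames: centroid (mean and SD across frames),
#' bandwidth (power-weighted SD around the centroid), flatness (geometric
#' over arithmetic mean of the power spectrum), and the 85% energy rolloff
#' frequency. Silent tracks yield `NA`s.
#'
#' @inheritParams volumeEnvelope
#' @return Named numeric vector (`spectral_centroid_mean`,
#'   `spectral_centroid_std`, `spectral_bandwidth_mean`,
#'   `spectral_flatness_mean`, `spectral_rolloff_mean`).
#' @export
spectralFeatures <- function(track, config = defaultConfig()) {
  out <- c(spectral_centroid_mean = NA_real_, spectral_centroid_std = NA_real_,
           spectral_bandwidth_mean = NA_real_,
           spectral_flatness_mean = NA_real_, spectral_rolloff_mean = NA_real_)
  af <- acousticFrames(samples(track), sampleRate(track), config$audio)
  sp <- which(af$speech)
  if (!length(sp)) return(out)
  fq <- af$freqs
  cent <- band <- flat <- roll <- numeric(length(sp))
  for (k in seq_along(sp)) {
    P <- af$pow[, sp[k]]
    tot <- sum(P)
    if (tot <= 0) { cent[k] <- NA; next }
    cent[k] <- sum(fq * P) / tot
    band[k] <- sqrt(sum((fq - cent[k])^2 * P) / tot)
    flat[k] <- exp(mean(log(P + 1e-300))) / mean(P)
    roll[k] <- fq[which(cumsum(P) >= config$audio$rolloff_quantile * tot)[1]]
  }
  out["spectral_centroid_mean"] <- mean(cent, na.rm = TRUE)
  out["spectral_centroid_std"] <- if (sum(!is.na(cent)) > 1L)
    stats::sd(cent, na.rm = TRUE) else 0
  out["spectral_bandwidth_mean"] <- mean(band, na.rm = TRUE)
  out["spectral_flatness_mean"] <- mean(flat, na.rm = TRUE)
  out["spectral_rolloff_mean"] <- mean(roll, na.rm = TRUE)
  out
}

#' Formant frequencies via linear prediction
#'
#' The track is first brought to the formant analysis rate (11,025 Hz;
#' standard practice, as an LPC order around 12 then covers the 0-5.5 kHz
#' band with one pole pair per expected resonance). Per voiced frame, a
#' pre-emphasized hann-windowed segment is fitted with
#' a Burg LPC model (default order 12); roots of the
#' prediction polynomial with bandwidth under 400 Hz inside (90 Hz,
#' Nyquist) are formant candidates, and the lowest three give F1-F3.
#' Session values aggregate frame estimates (means, SDs, and the
#' `f2_mean / f1_mean` ratio). Unvoiced-only audio yields `NA`s.
#'
#' @inheritParams volumeEnvelope
#' @return Named numeric vector (`f1_mean`, `f2_mean`, `f3_mean`,
#'   `f1_std`, `f2_std`, `f2_f1_ratio`).
#' @export
formantFeatures <- function(track, config = defaultConfig()) {
  out <- c(f1_mean = NA_real_, f2_mean = NA_real_, f3_mean = NA_real_,
           f1_std = NA_real_, f2_std = NA_real_, f2_f1_ratio = NA_real_)
  cfg <- config$audio
  if (sampleRate(track) > cfg$formant_rate) {
    track <- resampleAudio(track, cfg$formant_rate)
    scaleBy <- cfg$formant_rate / defaultConfig()$temporal$target_rate
    cfg$frame_length <- max(256L, round(cfg$frame_length * scaleBy))
    cfg$hop_length <- max(64L, round(cfg$hop_length * scaleBy))
  }
  x <- samples(track); sr <- sampleRate(track)
  af <- acousticFrames(x, sr, cfg)
  vFrames <- which(af$voiced)
  if (!length(vFrames)) return(out)
  ## pre-emphasis
  xe <- c(x[1], x[-1] - 0.97 * x[-length(x)])
  fl <- af$frameLength
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(fl) / (fl + 1))
  F1 <- F2 <- F3 <- rep(NA_real_, length(vFrames))
  for (k in seq_along(vFrames)) {
    s0 <- af$starts[vFrames[k]]
    seg <- xe[s0:min(length(xe), s0 + fl - 1L)]
    if (length(seg) < fl) next
    seg <- seg * win
    fit <- tryCatch(stats::ar.burg(seg, aic = FALSE,
                                   order.max = cfg$lpc_order,
                                   demean = TRUE),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$ar) < cfg$lpc_order) next
    rts <- polyroot(c(1, -fit$ar))      # roots in z^{-1}
    z <- 1 / rts
    ang <- Arg(z)
    fr <- ang * sr / (2 * pi)
    bw <- -sr / pi * log(pmin(Mod(z), 1 - 1e-12))
    ok <- fr > 90 & fr < sr / 2 - 50 & bw < 400
    fr <- sort(fr[ok])
    if (length(fr) >= 1L) F1[k] <- fr[1]
    if (length(fr) >= 2L) F2[k] <- fr[2]
    if (length(fr) >= 3L) F3[k] <- fr[3]
  }
  if (any(!is.na(F1))) {
    out["f1_mean"] <- mean(F1, na.rm = TRUE)
    out["f1_std"] <- if (sum(!is.na(F1)) > 1L) stats::sd(F1, na.rm = TRUE) else 0
  }
  if (any(!is.na(F2))) {
    out["f2_mean"] <- mean(F2, na.rm = TRUE)
    out["f2_std"] <- if (sum(!is.na(F2)) > 1L) stats::sd(F2, na.rm = TRUE) else 0
  }
  if (any(!is.na(F3))) out["f3_mean"] <- mean(F3, na.rm = TRUE)
  if (!is.na(out["f1_mean"]) && !is.na(out["f2_mean"]) && out["f1_mean"] > 0) {
    out["f2_f1_ratio"] <- out["f2_mean"] / out["f1_mean"]
  }
  out
}

#' Silent-pause statistics
#'
#' Pauses are maximal runs of frames below the silence threshold lasting at
#' least `min_pause` (default 300 ms), excluding leading and trailing
#' silence. `pause_rate` is pauses per second of response; `pause_mean_len`
#' is the mean pause duration in seconds (`NA` with zero pauses).
#'
#' @inheritParams volumeEnvelope
#' @return Named numeric vector (`pause_rate`, `pause_mean_len`).
#' @export
pauseFeatures <- function(track, config = defaultConfig()) {
  af <- acousticFrames(samples(track), sampleRate(track), config$audio)
  sp <- af$speech
  dur <- af$duration
  if (!any(sp)) return(c(pause_rate = NA_real_, pause_mean_len = NA_real_))
  lo <- which(sp)[1]; hi <- which(sp)[length(which(sp))]
  inner <- sp[lo:hi]
  run <- rle(inner)
  ## a run of k silent frames spans (k-1) hops plus one analysis window
  lens <- ((run$lengths[!run$values] - 1L) * af$hop + af$frameLength) / af$sr
  lens <- lens[lens >= config$audio$min_pause]
  c(pause_rate = length(lens) / dur,
    pause_mean_len = if (length(lens)) mean(lens) else NA_real_)
}

#' Extract the 28 acoustic features of a session
#'
#' Each response track is resampled to the analysis rate if needed, all
#' acoustic feature groups are computed per response, and the session value
#' of each feature is the unweighted mean over responses (missing response
#' values are excluded from the mean; a feature missing in every response
#' stays `NA`).
#'
#' @param tracks A list of [AudioTrack] objects (or a single track).
#' @param config Configuration list, see [defaultConfig()].
#' @return Named numeric vector with the 28 acoustic feature names of
#'   [featureRegistry()].
#' @export
extractAcoustic <- function(tracks, config = defaultConfig()) {
  if (is(tracks, "AudioTrack")) tracks <- list(tracks)
  if (!length(tracks)) stop("at least one response track is required")
  perResponse <- vapply(tracks, function(tr) {
    tr <- resampleAudio(tr, config$temporal$target_rate)
    vol <- volumeEnvelope(tr, config)$features
    pit <- pitchTrack(tr, config)$features
    c(pit[c("pitch_mean", "pitch_std", "pitch_range", "pitch_slope")],
      vol[c("vol_mean", "vol_std", "vol_range", "vol_slope", "ealvi")],
      perturbationFeatures(tr, config),
      spectralFeatures(tr, config),
      formantFeatures(tr, config),
      pauseFeatures(tr, config),
      voiced_fraction = unname(pit["voiced_fraction"]))
  }, numeric(28L))
  out <- rowMeans(perResponse, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  names(out) <- featureNames66("audio")
  out
}
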