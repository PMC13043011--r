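## Envelope-normalized carrier: a tone whose frame RMS equals the supplied
## amplitude envelope, so closed-form envelope oracles apply exactly.
envTone <- function(env, freq = 150, dur = 2, sr = 22050) {
  t <- seq_len(round(dur * sr)) / sr
  carrier <- sin(2 * pi * freq * t)
  carrier <- carrier / sqrt(mean(carrier^2))
  AudioTrack(pmin(1, pmax(-1, carrier * env(t))), sr)
}

test_that("volume features are exact on constant and ramping envelopes", {
  tr <- envTone(function(t) rep(0.2, length(t)))
  f <- volumeEnvelope(tr)$features
  expect_equal(unname(f["vol_std"]), 0, tolerance = 1e-3)
  expect_equal(unname(f["vol_slope"]), 0, tolerance = 1e-3)
  expect_lt(unname(f["vol_range"]), 1e-2)
  expect_equal(unname(f["vol_mean"]), 0.2, tolerance = 1e-2)

  ## RMS envelope ramping 0.1 -> 0.3 over 2 s: slope 0.1 per second
  tr <- envTone(function(t) 0.1 + 0.1 * t, dur = 2)
  f <- volumeEnvelope(tr)$features
  expect_equal(unname(f["vol_slope"]), 0.1, tolerance = 0.01)

  ## all-zero samples: volume features flagged missing
  z <- AudioTrack(rep(0, 22050), 22050)
  expect_true(all(is.na(volumeEnvelope(z)$features)))
})

test_that("pitch tracking recovers tones, glides, and rejects noise", {
  f <- pitchTrack(toneTrack(220, dur = 2))$features
  expect_lt(abs(f["pitch_mean"] - 220), 1)
  expect_lt(f["pitch_std"], 1)
  expect_equal(unname(f["voiced_fraction"]), 1, tolerance = 0.05)

  set.seed(41)
  noise <- AudioTrack(pmin(1, pmax(-1, rnorm(44100, sd = 0.2))), 22050)
  f <- pitchTrack(noise)$features
  expect_lt(unname(f["voiced_fraction"]), 0.1)

  ## linear glide 180 -> 260 Hz over 2 s: slope 40 Hz/s within 5%
  sr <- 22050; t <- seq_len(2 * sr) / sr
  phase <- 2 * pi * cumsum(180 + 40 * t) / sr
  glide <- AudioTrack(0.3 * sin(phase), sr)
  f <- pitchTrack(glide)$features
  expect_equal(unname(f["pitch_slope"]), 40, tolerance = 0.05)
})

test_that("jitter and shimmer vanish on strictly periodic pulse trains", {
  sr <- 22050
  x <- numeric(sr * 2)
  x[seq(1, length(x), by = 150)] <- 0.8      # exactly 147 Hz
  f <- perturbationFeatures(AudioTrack(x, sr))
  expect_equal(unname(f["jitter_local"]), 0, tolerance = 1e-8)
  expect_equal(unname(f["shimmer_local"]), 0, tolerance = 1e-8)
})

test_that("programmed jitter matches the period-sequence oracle", {
  set.seed(42)
  p <- baseParams(jitter_eps = 0.03, shimmer_eps = 0, pause_rate = 0,
                  rms_var = 0, f0_slope = 0)
  out <- synthAudio(p, duration = 3, returnCycles = TRUE)
  f <- perturbationFeatures(out$track)
  ## brute-force oracle on the generated period sequence
  periods <- diff(out$cycleTimes)
  oracle <- mean(abs(diff(periods))) / mean(periods)
  expect_equal(unname(f["jitter_local"]), oracle, tolerance = 0.1)
})

test_that("alternating cycle amplitudes give the hand-computed shimmer", {
  sr <- 22050
  amps <- rep(c(0.5, 0.55), 100)             # A and 1.1 A
  x <- numeric(150 * length(amps) + 1)
  x[1 + (seq_along(amps) - 1) * 150] <- amps
  f <- perturbationFeatures(AudioTrack(x, sr))
  ## hand computation on consecutive amplitude differences
  expected <- mean(abs(diff(amps))) / mean(amps)
  expect_equal(unname(f["shimmer_local"]), expected, tolerance = 0.02)
  expect_equal(unname(f["shimmer_db"]),
               mean(abs(20 * log10(amps[-1] / amps[-length(amps)]))),
               tolerance = 0.05)
})

test_that("spectral descriptors match single- and two-line spectra", {
  binWidth <- 22050 / 2048
  f <- spectralFeatures(toneTrack(1000, dur = 1))
  expect_lt(abs(f["spectral_centroid_mean"] - 1000), binWidth)
  expect_lt(f["spectral_flatness_mean"], 0.01)

  ## two equal tones at 500 and 1500 Hz: weighted-mean centroid at 1000 Hz
  sr <- 22050; t <- seq_len(sr) / sr
  x <- 0.25 * sin(2 * pi * 500 * t) + 0.25 * sin(2 * pi * 1500 * t)
  f <- spectralFeatures(AudioTrack(x, sr))
  expect_lt(abs(f["spectral_centroid_mean"] - 1000), binWidth)

  ## white noise approaches the flat-spectrum limit
  set.seed(43)
  noise <- AudioTrack(pmin(1, pmax(-1, rnorm(22050, sd = 0.2))), 22050)
  fn <- spectralFeatures(noise)
  expect_gt(fn["spectral_flatness_mean"], 0.3)
  expect_gt(fn["spectral_flatness_mean"], 20 * f["spectral_flatness_mean"])
})

test_that("formants recover a programmed 500/1500/2500 Hz vowel", {
  set.seed(44)
  p <- baseParams(f0_mean = 100, jitter_eps = 0.005, shimmer_eps = 0.02,
                  pause_rate = 0, formant1 = 500, formant2 = 1500,
                  formant3 = 2500)
  tr <- synthAudio(p, duration = 3)
  f <- formantFeatures(tr)
  expect_lt(abs(f["f1_mean"] - 500) / 500, 0.1)
  expect_lt(abs(f["f2_mean"] - 1500) / 1500, 0.1)
  expect_lt(abs(f["f3_mean"] - 2500) / 2500, 0.1)
  ## stationary filter: per-frame spread stays small
  expect_lt(f["f1_std"], 50)
  expect_lt(f["f2_std"], 100)
  expect_equal(unname(f["f2_f1_ratio"]), 3, tolerance = 0.2)
})

test_that("pause detection honors the minimum-duration threshold", {
  sr <- 22050
  tone <- function(dur) 0.3 * sin(2 * pi * 150 * seq_len(round(dur * sr)) / sr)
  f <- pauseFeatures(AudioTrack(tone(2), sr))
  expect_equal(unname(f["pause_rate"]), 0)

  gap <- AudioTrack(c(tone(1), rep(0, round(0.4 * sr)), tone(1)), sr)
  f <- pauseFeatures(gap)
  expect_equal(unname(f["pause_rate"]) * 2.4, 1, tolerance = 0.1)
  expect_equal(unname(f["pause_mean_len"]), 0.4, tolerance = 0.1)

  cfg <- defaultConfig(); cfg$audio$min_pause <- 0.5
  f <- pauseFeatures(gap, cfg)
  expect_equal(unname(f["pause_rate"]), 0)
})

test_that("ealvi counts low-volume frames per its definition", {
  expect_equal(ealvi(rep(0.2, 50)), 0)
  expect_equal(ealvi(c(rep(1, 25), rep(0.2, 25))), 0.5)
  ## enumeration oracle on a monotone ramp
  r <- seq(0.1, 1, length.out = 97)
  expect_equal(ealvi(r), mean(r < 0.5 * median(r)))
})

test_that("extractAcoustic aggregates responses into the 28-name registry", {
  set.seed(45)
  p <- baseParams(sentence_len = 5)
  tr <- synthAudio(p, duration = 2)
  a1 <- extractAcoustic(list(tr))
  expect_identical(names(a1), featureNames66("audio"))
  expect_identical(length(a1), 28L)
  ## four identical responses equal the single response
  a4 <- extractAcoustic(list(tr, tr, tr, tr))
  expect_equal(a4, a1)
})

test_that("amplitude scaling and time reversal behave as expected", {
  set.seed(46)
  p <- baseParams(pause_rate = 0.4, f0_slope = 4, rms_slope = 0.01)
  tr <- synthAudio(p, duration = 3)
  a <- extractAcoustic(list(tr))
  half <- AudioTrack(samples(tr) * 0.5, sampleRate(tr))
  ah <- extractAcoustic(list(half))
  invariant <- c("pitch_mean", "pitch_std", "jitter_local", "f1_mean",
                 "f2_mean", "spectral_flatness_mean", "voiced_fraction",
                 "ealvi", "pause_rate", "shimmer_local")
  expect_equal(ah[invariant], a[invariant], tolerance = 1e-6)
  expect_equal(unname(ah["vol_mean"]), unname(a["vol_mean"]) * 0.5,
               tolerance = 1e-6)
  expect_equal(unname(ah["vol_range"]), unname(a["vol_range"]) * 0.5,
               tolerance = 1e-6)
  expect_equal(unname(ah["vol_slope"]), unname(a["vol_slope"]) * 0.5,
               tolerance = 1e-6)

  ## time reversal flips the volume and pitch slopes
  rev <- AudioTrack(rev(samples(tr)), sampleRate(tr))
  ar <- extractAcoustic(list(rev))
  expect_equal(unname(ar["vol_slope"]), -unname(a["vol_slope"]),
               tolerance = 0.15)
  expect_equal(unname(ar["pitch_slope"]), -unname(a["pitch_slope"]),
               tolerance = 0.15)
})
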