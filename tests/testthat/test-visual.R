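test_that("blink detection finds rectangular pulses with correct rate", {
  tt <- fps30(10)
  ## constant zero: no events
  expect_identical(nrow(detectBlinks(makeStream(tt))), 0L)

  ## one 100 ms pulse at amplitude 0.9
  sig <- pulses(tt, 2, 0.1)
  st <- makeStream(tt, list(eyeBlinkLeft = sig, eyeBlinkRight = sig))
  ev <- detectBlinks(st)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$end - ev$start, 0.1, tolerance = 1 / 30)

  ## 3 pulses in 10 s -> 0.3 blinks/s
  sig <- pulses(tt, c(1, 4, 7), 0.1)
  st <- makeStream(tt, list(eyeBlinkLeft = sig, eyeBlinkRight = sig))
  ev <- detectBlinks(st)
  expect_identical(nrow(ev), 3L)
  v <- extractVisual(st)
  expect_equal(unname(v["blinks_per_s"]), 0.3, tolerance = 1e-6)
  ## blink_len equals the mean of event durations (brute force)
  expect_equal(unname(v["blink_len"]), mean(ev$end - ev$start))
})

test_that("events outside the duration bounds are discarded", {
  tt <- fps30(10)
  ## 20 ms pulse: below blink min duration
  st <- makeStream(tt, list(eyeBlinkLeft = pulses(tt, 2, 0.02),
                            eyeBlinkRight = pulses(tt, 2, 0.02)))
  expect_identical(nrow(detectBlinks(st)), 0L)
  ## 900 ms pulse: above blink max duration
  st <- makeStream(tt, list(eyeBlinkLeft = pulses(tt, 2, 0.9),
                            eyeBlinkRight = pulses(tt, 2, 0.9)))
  expect_identical(nrow(detectBlinks(st)), 0L)
})

test_that("yawns require sustained jawOpen above threshold", {
  tt <- fps30(10)
  expect_identical(nrow(detectYawns(makeStream(tt))), 0L)

  st <- makeStream(tt, list(jawOpen = pulses(tt, 3, 2.0, amp = 0.8)))
  ev <- detectYawns(st)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$end - ev$start, 2.0, tolerance = 2 / 30)

  ## 0.5 s burst is below the 1.5 s sustained minimum
  st <- makeStream(tt, list(jawOpen = pulses(tt, 3, 0.5, amp = 0.8)))
  expect_identical(nrow(detectYawns(st)), 0L)
})

test_that("eyelid droop is the masked mean outside blink events", {
  tt <- fps30(10)
  st <- makeStream(tt, list(eyeBlinkLeft = 0.2, eyeBlinkRight = 0.2))
  expect_equal(eyelidDroop(st), 0.2)

  ## baseline plus one blink pulse; the pulse is excluded from the mean
  sig <- pmax(0.2, pulses(tt, 5, 0.15))
  st <- makeStream(tt, list(eyeBlinkLeft = sig, eyeBlinkRight = sig))
  ev <- detectBlinks(st)
  expect_identical(nrow(ev), 1L)
  expect_equal(eyelidDroop(st, ev), 0.2)
  ## masked-mean oracle: brute-force mean over frames outside the event
  keep <- !(tt >= ev$start & tt < ev$end)
  expect_equal(eyelidDroop(st, ev), mean(sig[keep]))

  expect_equal(eyelidDroop(makeStream(tt)), 0)
})

test_that("gaze features follow the axis conventions", {
  tt <- fps30(5)
  g <- gazeFeatures(makeStream(tt))
  expect_equal(unname(g), c(0, 0, 0))

  st <- makeStream(tt, list(eyeLookDownLeft = 0.4, eyeLookDownRight = 0.4))
  g <- gazeFeatures(st)
  expect_equal(unname(g["gaze_down_dist"]), 0.4)
  expect_equal(unname(g["gaze_y_dist"]), 0.4)
  expect_equal(unname(g["gaze_x_dist"]), 0)

  ## upward gaze does not count as downward
  st <- makeStream(tt, list(eyeLookUpLeft = 0.4, eyeLookUpRight = 0.4))
  g <- gazeFeatures(st)
  expect_equal(unname(g["gaze_down_dist"]), 0)
  expect_equal(unname(g["gaze_y_dist"]), 0.4)
})

test_that("expressivity features match their definitions", {
  tt <- fps30(5)
  segs <- data.frame(start = 0, end = 5)
  ## frozen face
  e <- expressivityFeatures(makeStream(tt), segs)
  expect_equal(unname(e["affect_measure"]), 0)
  expect_equal(unname(e["movement_speech_measure"]), 0)
  expect_equal(unname(e["eye_movements_per_s"]), 0)

  ## mouth curvature arithmetic
  st <- makeStream(tt, list(mouthSmileLeft = 0.6, mouthSmileRight = 0.6,
                            mouthFrownLeft = 0.1, mouthFrownRight = 0.1))
  e <- expressivityFeatures(st, segs)
  expect_equal(unname(e["mouth_curvature"]), 0.5)

  ## uniform translation of 0.01 units/frame at 30 fps during speech
  tt2 <- fps30(0.5)
  st <- makeStream(tt2, landmarkOffsets = 0.01 * seq_along(tt2),
                   lmValue = 0.2)
  e <- expressivityFeatures(st, segs)
  ## displacement-sum oracle: per-step xy displacement is 0.01*sqrt(2)
  expect_equal(unname(e["movement_speech_measure"]), 0.01 * sqrt(2) * 30,
               tolerance = 1e-6)

  ## without speech segments the movement measure is flagged missing
  e <- expressivityFeatures(st, NULL)
  expect_true(is.na(e["movement_speech_measure"]))
})

test_that("extractVisual returns exactly the 13 canonical features", {
  tt <- fps30(10)
  v <- extractVisual(makeStream(tt))
  expect_identical(names(v), featureNames66("visual"))
  expect_identical(length(v), 13L)
  ## static centered closed-mouth face
  expect_equal(unname(v[c("blinks_per_s", "yawns_per_s",
                          "eye_movements_per_s", "affect_measure")]),
               rep(0, 4))
  ## event-length features are reported missing, not silently zero
  expect_true(is.na(v["blink_len"]) && is.na(v["yawn_len"]))
})

test_that("synthetic blink rate survives the extraction round trip", {
  set.seed(31)
  p <- baseParams(blink_rate = 0.4, yawn_rate = 0)
  st <- synthLandmarks(p, duration = 60)
  v <- extractVisual(st)
  ## central 95% Poisson interval for mean 24 over 60 s
  n <- unname(v["blinks_per_s"]) * 60
  expect_gte(n, qpois(0.025, 24))
  expect_lte(n, qpois(0.975, 24))
})

test_that("features are invariant to time shift and depth scaling", {
  ## deterministic stream: irregular timing, blink pulses, gaze steps
  ## (isolated saccades far above the median velocity, so event detection
  ## has no near-threshold flicker)
  set.seed(32)
  tt <- cumsum(c(0, 1 / runif(700, 30, 60)))
  tt <- tt[tt <= 20]
  blink <- pulses(tt, c(2, 9, 15), 0.15)
  down <- 0.1 + pulses(tt, c(5, 11), 2, amp = 0.3)
  st <- makeStream(tt, list(eyeBlinkLeft = blink, eyeBlinkRight = blink,
                            eyeLookDownLeft = down, eyeLookDownRight = down,
                            mouthSmileLeft = 0.2 + 0.1 * sin(tt),
                            jawOpen = pulses(tt, 7, 1.8, amp = 0.8)))
  v0 <- extractVisual(st)

  ## shift all timestamps by a constant
  shifted <- LandmarkStream(frameTimes(st) + 37.5, landmarks(st),
                            blendshapes(st))
  ev0 <- detectBlinks(interpolateStream(st))
  ev1 <- detectBlinks(interpolateStream(shifted))
  expect_equal(ev1$start, ev0$start + 37.5, tolerance = 1e-9)
  expect_equal(extractVisual(shifted), v0, tolerance = 1e-9)

  ## uniform scaling of z leaves everything unchanged (movement is xy-only)
  lmz <- landmarks(st); lmz[, , 3] <- lmz[, , 3] * 5
  zscaled <- LandmarkStream(frameTimes(st), lmz, blendshapes(st))
  expect_equal(extractVisual(zscaled), v0, tolerance = 1e-9)
})
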