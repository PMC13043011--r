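shortConfig <- function(...) {
  pt <- paramDefaults()
  pt["sentence_len", "base"] <- 5
  pt["speech_rate", "base"] <- 3
  cohortConfig(..., paramTable = pt)
}

test_that("the generator is fully deterministic under a seed", {
  cfg <- shortConfig(nParticipants = 3, sessionsPerParticipant = 2, seed = 9)
  a <- simulateFeatureTable(cfg)
  b <- simulateFeatureTable(cfg)
  expect_identical(SummarizedExperiment::assay(a$se),
                   SummarizedExperiment::assay(b$se))
  expect_identical(a$truth, b$truth)
  c3 <- simulateFeatureTable(shortConfig(nParticipants = 3,
                                         sessionsPerParticipant = 2,
                                         seed = 10))
  expect_false(identical(SummarizedExperiment::assay(a$se),
                         SummarizedExperiment::assay(c3$se)))
})

test_that("full synthesis writes byte-identical bundles under one seed", {
  cfg <- shortConfig(nParticipants = 2, sessionsPerParticipant = 1, seed = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateCohort(cfg, outDir = d1)
  simulateCohort(cfg, outDir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("synthetic landmark frames carry 478 points and 52 blendshapes", {
  set.seed(61)
  st <- synthLandmarks(baseParams(), duration = 10)
  expect_identical(dim(landmarks(st))[2:3], c(478L, 3L))
  expect_identical(ncol(blendshapes(st)), 52L)
  ## irregular timing in the 30-60 fps band
  dt <- diff(frameTimes(st))
  expect_true(all(dt > 1 / 61 & dt < 1 / 29))
  expect_gt(stats::sd(dt), 0)
})

test_that("programmed blink rates drive detected event counts", {
  set.seed(62)
  st <- synthLandmarks(baseParams(blink_rate = 0), duration = 30)
  expect_identical(nrow(detectBlinks(interpolateStream(st))), 0L)

  st <- synthLandmarks(baseParams(blink_rate = 0.4, yawn_rate = 0),
                       duration = 120)
  n <- nrow(detectBlinks(interpolateStream(st)))
  expect_gte(n, qpois(0.025, 48))
  expect_lte(n, qpois(0.975, 48))
})

test_that("synthetic transcripts follow the 5-agent/4-participant protocol", {
  set.seed(63)
  tx <- synthTranscript(baseParams())$transcript
  tu <- turns(tx)
  expect_identical(sum(tu$speaker == "participant"), 4L)
  expect_identical(sum(tu$speaker == "agent"), 5L)
  expect_identical(tu$speaker[1], "agent")
  expect_true(all(diff(tu$start) > 0))

  ## filler rate 0 -> no hesitations downstream
  tx0 <- synthTranscript(baseParams(filler_rate = 0))$transcript
  expect_equal(unname(extractText(tx0)["hesitations_per_s"]), 0)
})

test_that("programmed long-word proportion yields the formula Fog value", {
  set.seed(64)
  p <- baseParams(long_word_prop = 0.1, sentence_len = 50, filler_rate = 0)
  tx <- synthTranscript(p)$transcript
  pt <- participantTurns(tx)
  for (i in seq_len(2)) {
    tk <- tokenizeText(pt$text[i])
    syl <- countSyllables(tk$tokens)
    expected <- 0.4 * (length(tk$tokens) / length(tk$sentences) +
                         100 * mean(syl >= 3))
    expect_equal(unname(readability(pt$text[i])["gunning_fog_complexity"]),
                 expected, tolerance = 1e-9)
  }
})

test_that("audio synthesis round-trips programmed pitch, slope, and purity", {
  set.seed(65)
  p <- baseParams(jitter_eps = 0, shimmer_eps = 0, f0_slope = 0,
                  rms_var = 0, pause_rate = 0, f0_mean = 200)
  tr <- synthAudio(p, duration = 3)
  f <- pitchTrack(tr)$features
  expect_lt(abs(f["pitch_mean"] - 200), 2)
  pert <- perturbationFeatures(tr)
  expect_lt(pert["jitter_local"], 0.005)
  expect_lt(pert["shimmer_local"], 0.01)

  p <- baseParams(rms_slope = 0.02, rms_var = 0, pause_rate = 0)
  f <- volumeEnvelope(synthAudio(p, duration = 4))$features
  expect_equal(unname(f["vol_slope"]), 0.02, tolerance = 0.1)
})

test_that("clinical scores always respect instrument ranges", {
  set.seed(66)
  ## extreme latents force clipping
  lat <- data.frame(participant = rep(sprintf("P%02d", 1:10), each = 2),
                    session = rep(1:2, 10),
                    depression = rnorm(20, sd = 4),
                    fatigue = rnorm(20, sd = 4),
                    cognition = rnorm(20, sd = 4))
  cfg <- shortConfig(nParticipants = 10, sessionsPerParticipant = 2,
                     seed = 66)
  tab <- simulateFeatureTable(cfg, latents = lat)
  cd <- as.data.frame(SummarizedExperiment::colData(tab$se))
  expect_true(all(cd$phq9_total >= 0 & cd$phq9_total <= 27))
  expect_true(all(cd$cfs_physical >= 0 & cd$cfs_physical <= 28))
  expect_true(all(cd$cfs_affective >= 0 & cd$cfs_affective <= 16))
  expect_true(all(cd$cfs_cognitive >= 0 & cd$cfs_cognitive <= 16))
  expect_equal(cd$cfs_total,
               cd$cfs_physical + cd$cfs_affective + cd$cfs_cognitive)
  expect_true(all(cd$tmt_a_seconds > 0 & cd$tmt_b_seconds > 0))
})

test_that("generator parameters stay inside their physical ranges", {
  set.seed(67)
  cfg <- shortConfig(nParticipants = 20, sessionsPerParticipant = 1,
                     seed = 67, effects = defaultEffects(2))
  tab <- simulateFeatureTable(cfg)
  pd <- paramDefaults()
  for (pn in pd$param) {
    expect_true(all(tab$truth[[pn]] >= pd[pn, "min"] - 1e-9 &
                      tab$truth[[pn]] <= pd[pn, "max"] + 1e-9),
                label = pn)
  }
})

test_that("the fast path plants couplings the full pipeline can see", {
  ## strong fatigue -> volume-variability coupling shows up in vol_std
  eff <- defaultEffects(0)
  eff["fatigue", "rms_var"] <- -0.9
  cfg <- shortConfig(nParticipants = 40, sessionsPerParticipant = 1,
                     seed = 68, effects = eff)
  tab <- simulateFeatureTable(cfg)
  x <- SummarizedExperiment::assay(tab$se)["vol_std", ]
  y <- as.data.frame(SummarizedExperiment::colData(tab$se))$cfs_total
  ct <- pearsonTest(x, y)
  expect_lt(ct$r, 0)
  expect_lt(ct$p, 0.05)
})
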