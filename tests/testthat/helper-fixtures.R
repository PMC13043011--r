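## Fixture builders shared across the suite. Everything is generated in
## code; no binary fixtures.

baseParams <- function(...) {
  p <- stats::setNames(paramDefaults()$base, paramDefaults()$param)
  over <- list(...)
  p[names(over)] <- unlist(over)
  p
}

## a stream with constant landmarks and caller-chosen blendshape signals;
## any unspecified blendshape is 0
makeStream <- function(timestamps, signals = list(), lmValue = 0.5,
                       landmarkOffsets = NULL) {
  n <- length(timestamps)
  bs <- matrix(0, n, 52L, dimnames = list(NULL, blendshapeNames()))
  for (nm in names(signals)) {
    v <- signals[[nm]]
    bs[, nm] <- if (length(v) == 1L) rep(v, n) else v
  }
  lm <- array(lmValue, dim = c(n, 478L, 3L))
  if (!is.null(landmarkOffsets)) {      # per-frame uniform xy translation
    for (i in seq_len(n)) {
      lm[i, , 1] <- lmValue + landmarkOffsets[i]
      lm[i, , 2] <- lmValue + landmarkOffsets[i]
    }
  }
  LandmarkStream(timestamps, lm, bs)
}

## uniform 30 fps timestamps over [0, dur]
fps30 <- function(dur) seq(0, dur, by = 1 / 30)

toneTrack <- function(freq, dur = 1, sr = 22050, amp = 0.3, idx = 1L) {
  t <- seq_len(round(dur * sr)) / sr
  AudioTrack(amp * sin(2 * pi * freq * t), sr, idx)
}

## a rectangular activation pulse train on the given time grid
pulses <- function(timestamps, starts, width, amp = 0.9) {
  sig <- numeric(length(timestamps))
  for (s in starts) sig[timestamps >= s & timestamps < s + width] <- amp
  sig
}

## simple transcript: agent/participant alternating with given texts
simpleTranscript <- function(respTexts, respDur = 5, latency = 1,
                             agentDur = 3, speechRate = 2.5,
                             withWords = TRUE) {
  tcur <- 0; turnsList <- list(); wordsList <- list()
  for (k in seq_along(respTexts)) {
    turnsList[[length(turnsList) + 1L]] <- data.frame(
      speaker = "agent", text = "How are you?", start = tcur,
      end = tcur + agentDur, stringsAsFactors = FALSE)
    tcur <- tcur + agentDur
    toks <- tokenizeText(respTexts[k])$tokens
    start <- tcur + latency
    wdur <- 0.8 / speechRate; wgap <- 0.2 / speechRate
    ws <- start + (seq_along(toks) - 1L) * (wdur + wgap)
    we <- ws + wdur
    end <- if (length(we)) we[length(we)] else start + respDur
    turnsList[[length(turnsList) + 1L]] <- data.frame(
      speaker = "participant", text = respTexts[k], start = start,
      end = end, stringsAsFactors = FALSE)
    if (withWords && length(toks)) {
      wordsList[[length(wordsList) + 1L]] <- data.frame(
        turn = 2L * k, token = toks, start = ws, end = we,
        stringsAsFactors = FALSE)
    }
    tcur <- end + 0.5
  }
  turnsList[[length(turnsList) + 1L]] <- data.frame(
    speaker = "agent", text = "Take care.", start = tcur,
    end = tcur + agentDur, stringsAsFactors = FALSE)
  Transcript(do.call(rbind, turnsList),
             if (length(wordsList)) do.call(rbind, wordsList) else NULL)
}

## tiny cohort SummarizedExperiment built directly from a feature matrix
tinyCohortSE <- function(mat, participants, sessions,
                         scores = NULL) {
  n <- ncol(mat)
  if (is.null(scores)) {
    scores <- data.frame(phq9_total = rep(5, n), cfs_total = rep(20, n),
                         cfs_physical = rep(10, n), cfs_affective = rep(5, n),
                         cfs_cognitive = rep(5, n),
                         tmt_a_seconds = rep(30, n),
                         tmt_b_seconds = rep(60, n),
                         tmt_total_seconds = rep(90, n))
  }
  full <- matrix(NA_real_, 66L, n, dimnames = list(featureNames66(), NULL))
  full[rownames(mat), ] <- mat
  info <- data.frame(participant_id = participants,
                     session_id = sessions,
                     timestamp = sprintf("2025-03-%02dT09:00:00Z",
                                         seq_len(n)),
                     scores, stringsAsFactors = FALSE)
  makeCohortSE(full, info)
}

## brute-force Pearson r and two-sided p from the defining sums
bruteForcePearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  r <- num / den
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}
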