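#' Write a session bundle to disk
#'
#' Serializes a [CheckinSession] as a plain-text/WAV bundle directory:
#' `landmarks.jsonl` (one frame per line with fields `t`, `lm` — a flat
#' 478x3 row-major array — and `bs`, a name-to-score map), one
#' `response_<k>.wav` per participant response (mono 16-bit PCM),
#' `transcript.json`, `clinical.json` and `meta.json`.
#'
#' @param session A [CheckinSession].
#' @param path Bundle directory (created if needed).
#' @return `path`, invisibly.
#' @seealso [readSession()]
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "CheckinSession"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  st <- landmarkStream(session)
  lm <- landmarks(st); bs <- blendshapes(st); tt <- frameTimes(st)
  con <- file(file.path(path, "landmarks.jsonl"), "w")
  lines <- vapply(seq_along(tt), function(i) {
    jsonlite::toJSON(list(
      t = tt[i],
      lm = as.numeric(t(lm[i, , ])),     # x1,y1,z1,x2,...
      bs = as.list(stats::setNames(as.numeric(bs[i, ]), colnames(bs)))),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, con)
  close(con)

  for (tr in audioTracks(session)) {
    writeWav(samples(tr), sampleRate(tr),
             file.path(path, sprintf("response_%d.wav", tr@responseIndex)))
  }

  tx <- transcript(session)
  tu <- turns(tx); wo <- wordTimings(tx)
  turnList <- lapply(seq_len(nrow(tu)), function(i) {
    w <- wo[wo$turn == i, , drop = FALSE]
    list(speaker = tu$speaker[i], text = tu$text[i],
         start = tu$start[i], end = tu$end[i],
         words = lapply(seq_len(nrow(w)), function(j) {
           list(token = w$token[j], start = w$start[j], end = w$end[j])
         }))
  })
  jsonlite::write_json(list(turns = turnList),
                       file.path(path, "transcript.json"),
                       auto_unbox = TRUE, digits = NA)

  cs <- clinicalScores(session)
  jsonlite::write_json(list(
    phq9_total = cs@phq9Total,
    cfs_physical = cs@cfsPhysical, cfs_affective = cs@cfsAffective,
    cfs_cognitive = cs@cfsCognitive,
    tmt_a_seconds = cs@tmtASeconds, tmt_b_seconds = cs@tmtBSeconds),
    file.path(path, "clinical.json"), auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(list(
    participant_id = participantId(session), session_id = sessionId(session),
    timestamp = sessionTimestamp(session)),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Loads and fully validates a bundle written by [writeSession()] (or any
#' bundle following the same dialect). All type invariants are enforced:
#' 478 landmarks and 52 blendshapes per frame, strictly increasing
#' timestamps, one WAV response per participant turn, instrument score
#' ranges.
#'
#' @param path Bundle directory.
#' @return A validated [CheckinSession].
#' @export
readSession <- function(path) {
  needFile <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) stop("session bundle is missing file: ", f)
    p
  }
  meta <- jsonlite::read_json(needFile("meta.json"), simplifyVector = TRUE)
  clin <- jsonlite::read_json(needFile("clinical.json"), simplifyVector = TRUE)
  cs <- ClinicalScores(clin$phq9_total, clin$cfs_physical, clin$cfs_affective,
                       clin$cfs_cognitive, clin$tmt_a_seconds,
                       clin$tmt_b_seconds)

  lines <- readLines(needFile("landmarks.jsonl"))
  n <- length(lines)
  tt <- numeric(n)
  lm <- array(NA_real_, dim = c(n, landmarkCount(), 3L))
  bs <- matrix(NA_real_, n, 52L, dimnames = list(NULL, blendshapeNames()))
  for (i in seq_len(n)) {
    fr <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
    if (length(fr$lm) != landmarkCount() * 3L) {
      stop(sprintf("landmark frame %d has %d points (expected %d)",
                   i, length(fr$lm) %/% 3L, landmarkCount()))
    }
    if (length(fr$bs) != 52L) {
      stop(sprintf("landmark frame %d has %d blendshapes (expected 52)",
                   i, length(fr$bs)))
    }
    tt[i] <- fr$t
    lm[i, , ] <- matrix(as.numeric(fr$lm), ncol = 3L, byrow = TRUE)
    bs[i, ] <- as.numeric(unlist(fr$bs)[blendshapeNames()])
  }
  stream <- LandmarkStream(tt, lm, bs)

  txj <- jsonlite::read_json(needFile("transcript.json"))
  tu <- do.call(rbind, lapply(txj$turns, function(t) {
    data.frame(speaker = t$speaker, text = t$text,
               start = t$start, end = t$end, stringsAsFactors = FALSE)
  }))
  wo <- do.call(rbind, lapply(seq_along(txj$turns), function(i) {
    ws <- txj$turns[[i]]$words
    if (is.null(ws) || !length(ws)) return(NULL)
    data.frame(turn = i,
               token = vapply(ws, function(w) w$token, character(1)),
               start = vapply(ws, function(w) as.numeric(w$start), numeric(1)),
               end = vapply(ws, function(w) as.numeric(w$end), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  tx <- Transcript(tu, wo)

  nResp <- sum(tu$speaker == "participant")
  tracks <- vector("list", nResp)
  for (k in seq_len(nResp)) {
    wavPath <- file.path(path, sprintf("response_%d.wav", k))
    if (!file.exists(wavPath)) {
      stop(sprintf(
        "session bundle has %d participant turns but response_%d.wav is missing",
        nResp, k))
    }
    w <- readWav(wavPath)
    tracks[[k]] <- AudioTrack(w$samples, w$sampleRate, k)
  }

  CheckinSession(meta$participant_id, meta$session_id, meta$timestamp,
                 stream, tracks, tx, cs)
}
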