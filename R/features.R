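#' Extract the full 66-feature vector for one session
#'
#' Runs the temporal normalization (landmark interpolation to the target
#' fps, audio resampling to the analysis rate) and all three modality
#' extractors, returning the session's feature vector in registry order.
#'
#' @param session A [CheckinSession].
#' @param config Configuration list, see [defaultConfig()].
#' @param lexicons Lexicon list from [loadLexicons()].
#' @return Named numeric vector of length 66 (see [featureRegistry()]);
#'   undefined features are `NA`.
#' @export
extractFeatures <- function(session, config = defaultConfig(),
                            lexicons = loadLexicons()) {
  vis <- extractVisual(landmarkStream(session), transcript(session), config)
  aud <- extractAcoustic(audioTracks(session), config)
  txt <- extractText(transcript(session), config, lexicons)
  out <- c(vis, aud, txt)
  stopifnot(identical(names(out), featureNames66()))
  out
}

#' Extract a cohort of sessions into a SummarizedExperiment
#'
#' Applies [extractFeatures()] to every session and assembles the cohort
#' feature table: a [SummarizedExperiment::SummarizedExperiment] with one
#' `features` assay (66 features x sessions), the feature registry as
#' rowData, and participant/session identifiers plus clinical scores as
#' colData. Corrupt bundles are skipped with a warning so one bad session
#' does not abort a cohort.
#'
#' @param x Either a list of [CheckinSession] objects or a path to a
#'   directory whose subdirectories are session bundles (see
#'   [readSession()]).
#' @param config Configuration list, see [defaultConfig()].
#' @return A `SummarizedExperiment`.
#' @export
extractCohort <- function(x, config = defaultConfig()) {
  lexicons <- loadLexicons()
  if (is.character(x)) {
    dirs <- list.dirs(x, recursive = FALSE)
    sessions <- list()
    for (d in dirs) {
      s <- tryCatch(readSession(d), error = function(e) {
        warning("skipping corrupt session bundle ", basename(d), ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (!is.null(s)) sessions[[length(sessions) + 1L]] <- s
    }
  } else sessions <- x
  if (!length(sessions)) stop("no readable sessions")

  mat <- vapply(sessions, function(s) {
    tryCatch(extractFeatures(s, config, lexicons), error = function(e) {
      warning("feature extraction failed for session ", sessionId(s), ": ",
              conditionMessage(e), call. = FALSE)
      stats::setNames(rep(NA_real_, 66L), featureNames66())
    })
  }, numeric(66L))
  colnames(mat) <- vapply(sessions, sessionId, character(1))

  cd <- do.call(rbind, lapply(sessions, function(s) {
    sv <- scoreVector(clinicalScores(s))
    data.frame(participant_id = participantId(s),
               session_id = sessionId(s),
               timestamp = sessionTimestamp(s),
               t(sv), stringsAsFactors = FALSE)
  }))
  rownames(cd) <- colnames(mat)

  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    rowData = S4Vectors::DataFrame(featureRegistry()),
    colData = S4Vectors::DataFrame(cd))
}

#' Build a cohort SummarizedExperiment from a feature matrix
#'
#' Lower-level constructor used by the synthetic generator's fast path and
#' by CSV import: wraps a 66 x sessions matrix plus a session-metadata
#' frame into the same container [extractCohort()] produces.
#'
#' @param mat Numeric matrix, 66 features x sessions, rownames =
#'   [featureNames66()].
#' @param sessionInfo data.frame with one row per column of `mat`
#'   containing at least `participant_id`, `session_id`, `timestamp`, and
#'   the clinical score columns.
#' @return A `SummarizedExperiment`.
#' @export
makeCohortSE <- function(mat, sessionInfo) {
  stopifnot(identical(rownames(mat), featureNames66()),
            nrow(sessionInfo) == ncol(mat))
  colnames(mat) <- sessionInfo$session_id
  rownames(sessionInfo) <- sessionInfo$session_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    rowData = S4Vectors::DataFrame(featureRegistry()),
    colData = S4Vectors::DataFrame(sessionInfo))
}

#' Write / read the long-format feature CSV
#'
#' The interchange format for the feature table: one row per session x
#' feature with columns `participant_id`, `session_id`, `timestamp`,
#' `feature`, `modality`, `value`, plus a companion scores CSV with one row
#' per session.
#'
#' @param se Cohort `SummarizedExperiment` from [extractCohort()].
#' @param featurePath,scorePath Output CSV paths (`scorePath` optional).
#' @return `featurePath`, invisibly.
#' @export
writeFeatureCSV <- function(se, featurePath, scorePath = NULL) {
  mat <- SummarizedExperiment::assay(se, "features")
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  reg <- featureRegistry()
  long <- do.call(rbind, lapply(seq_len(ncol(mat)), function(j) {
    data.frame(participant_id = cd$participant_id[j],
               session_id = cd$session_id[j],
               timestamp = cd$timestamp[j],
               feature = rownames(mat),
               modality = reg[rownames(mat), "modality"],
               value = mat[, j], stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, featurePath, row.names = FALSE)
  if (!is.null(scorePath)) utils::write.csv(cd, scorePath, row.names = FALSE)
  invisible(featurePath)
}

#' @rdname writeFeatureCSV
#' @param featureCSV,scoreCSV Paths written by `writeFeatureCSV`.
#' @export
readFeatureCSV <- function(featureCSV, scoreCSV) {
  long <- utils::read.csv(featureCSV, stringsAsFactors = FALSE)
  cd <- utils::read.csv(scoreCSV, stringsAsFactors = FALSE)
  ids <- unique(long$session_id)
  mat <- matrix(NA_real_, 66L, length(ids),
                dimnames = list(featureNames66(), ids))
  for (j in seq_along(ids)) {
    sub <- long[long$session_id == ids[j], ]
    mat[sub$feature, j] <- sub$value
  }
  cd <- cd[match(ids, cd$session_id), , drop = FALSE]
  makeCohortSE(mat, cd)
}
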