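## Within-person composite risk score: z-score each significant feature
## against the participant's own sessions, align signs with the feature's
## correlation direction, and sum.

#' Within-participant z-scores
#'
#' `(v - mean(v)) / sd(v)` with the sample SD over the participant's
#' sessions. A constant series returns all zeros (deviation from a flat
#' personal baseline is zero by convention); a single session is an error
#' because a personal baseline is undefined.
#'
#' @param values Numeric vector of one participant's per-session values.
#' @return Numeric vector of z-scores.
#' @export
zscoreWithin <- function(values) {
  if (length(values) < 2L) {
    stop("within-participant z-scores require at least 2 sessions")
  }
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(0, length(values)))
  (values - mean(values, na.rm = TRUE)) / s
}

measureColumn <- function(measure) {
  switch(measure, depression = "phq9_total", fatigue = "cfs_total",
         stop("measure must be 'depression' or 'fatigue'"))
}

#' Composite within-person risk score
#'
#' For one clinical construct, the features significantly correlated with
#' the corresponding total score (PHQ-9 for depression, CFS total for
#' fatigue) are z-scored within each participant and summed with
#' directionality from the sign of each feature's baseline correlation:
#' `risk(session) = sum over significant features of sign(r) * z(session)`.
#' Missing feature values contribute 0 (flagged in the output) so
#' longitudinal series stay contiguous. Participants need >= 2 sessions; a
#' composite built from a single significant feature is emitted with a
#' warning since a one-feature composite is of limited meaning.
#'
#' @param se Cohort `SummarizedExperiment` with all sessions (not baseline
#'   selected).
#' @param correlations `results` data.frame from [correlateAll()] run on
#'   the baseline cohort; supplies significance and signs, which are frozen
#'   into the output metadata.
#' @param measure `"depression"` or `"fatigue"`.
#' @return data.frame with columns `participant_id`, `session_id`,
#'   `timestamp`, `risk_score`, `n_missing_features`; per-feature
#'   contributions in `attr(, "contributions")` (long data.frame) and the
#'   frozen feature signs in `attr(, "signs")`.
#' @export
compositeRisk <- function(se, correlations, measure = c("depression",
                                                        "fatigue")) {
  measure <- match.arg(measure)
  mcol <- measureColumn(measure)
  sig <- correlations[correlations$measure == mcol &
                        correlations$significant & !is.na(correlations$r), ,
                      drop = FALSE]
  if (!nrow(sig)) {
    stop("no significant features for ", measure,
         ": the composite risk score is undefined")
  }
  if (nrow(sig) == 1L) {
    warning("only one significant feature for ", measure,
            "; a single-feature composite is of limited meaning")
  }
  signs <- stats::setNames(sign(sig$r), sig$feature)

  mat <- SummarizedExperiment::assay(se, "features")
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  out <- NULL; contrib <- NULL
  for (pid in unique(cd$participant_id)) {
    cols <- which(cd$participant_id == pid)
    if (length(cols) < 2L) next
    cols <- cols[order(cd$timestamp[cols], cd$session_id[cols])]
    z <- matrix(0, length(signs), length(cols),
                dimnames = list(names(signs), cd$session_id[cols]))
    nMissing <- integer(length(cols))
    for (f in names(signs)) {
      v <- mat[f, cols]
      miss <- is.na(v)
      if (all(miss)) { nMissing <- nMissing + 1L; next }
      if (any(miss)) {
        nMissing[miss] <- nMissing[miss] + 1L
        v[miss] <- mean(v, na.rm = TRUE)   # z = 0 contribution
      }
      z[f, ] <- zscoreWithin(v)
    }
    zc <- z * signs
    out <- rbind(out, data.frame(
      participant_id = pid, session_id = cd$session_id[cols],
      timestamp = cd$timestamp[cols], risk_score = colSums(zc),
      n_missing_features = nMissing, stringsAsFactors = FALSE))
    contrib <- rbind(contrib, data.frame(
      participant_id = pid,
      session_id = rep(cd$session_id[cols], each = nrow(zc)),
      feature = rep(rownames(zc), length(cols)),
      contribution = as.numeric(zc), stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(participant_id = character(), session_id = character(),
                      timestamp = character(), risk_score = numeric(),
                      n_missing_features = integer())
  }
  rownames(out) <- NULL
  attr(out, "contributions") <- contrib
  attr(out, "signs") <- signs
  attr(out, "measure") <- measure
  out
}

#' Longitudinal risk report for a cohort
#'
#' Runs [compositeRisk()] for depression and fatigue over every
#' participant with at least 2 sessions and returns plot-ready series.
#'
#' @inheritParams compositeRisk
#' @return Named list (`depression`, `fatigue`) of risk data.frames (an
#'   element is `NULL`, with a diagnostic message, when the construct has
#'   no significant features or no eligible participants).
#' @export
riskReport <- function(se, correlations) {
  out <- list()
  for (m in c("depression", "fatigue")) {
    out[[m]] <- tryCatch(
      suppressWarnings(compositeRisk(se, correlations, m)),
      error = function(e) {
        message("risk series for ", m, " unavailable: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(out[[m]]) && !nrow(out[[m]])) {
      message("risk series for ", m,
              ": no participant has 2 or more sessions")
    }
  }
  out
}

#' Plot a participant's risk trajectory
#'
#' Base-graphics longitudinal plot of composite risk scores by session
#' order, one line per participant.
#'
#' @param risk data.frame from [compositeRisk()].
#' @param main Plot title.
#' @return Invisibly, `risk`.
#' @export
plotRiskSeries <- function(risk, main = "Composite risk score") {
  if (!nrow(risk)) { message("nothing to plot"); return(invisible(risk)) }
  pids <- unique(risk$participant_id)
  cols <- grDevices::hcl.colors(max(3L, length(pids)), "Dark 3")
  ylim <- range(risk$risk_score)
  maxSess <- max(table(risk$participant_id))
  graphics::plot(NA, xlim = c(1, maxSess), ylim = ylim,
                 xlab = "session", ylab = "risk score", main = main)
  graphics::abline(h = 0, lty = 3, col = "grey50")
  for (i in seq_along(pids)) {
    r <- risk[risk$participant_id == pids[i], ]
    graphics::lines(seq_len(nrow(r)), r$risk_score, col = cols[i], type = "b",
                    pch = 16)
  }
  graphics::legend("topleft", legend = pids, col = cols[seq_along(pids)],
                   lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(risk)
}
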