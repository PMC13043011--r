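## Baseline correlation stage: earliest-session selection, single-pass
## 2-SD outlier removal per feature, Pearson r/p per feature x clinical
## measure, and the modality-wise significance count table.

#' Clinical measures and subscales used in the correlation stage
#' @return Character vector of colData column names.
#' @export
clinicalMeasures <- function() {
  c("phq9_total", "cfs_total", "cfs_physical", "cfs_affective",
    "cfs_cognitive", "tmt_a_seconds", "tmt_b_seconds", "tmt_total_seconds")
}

#' Select each participant's baseline (earliest) session
#'
#' Only the earliest sample per participant enters the cross-sectional
#' correlation analysis; later sessions are reserved for within-person
#' monitoring. Ties on timestamp break deterministically to the lowest
#' session id.
#'
#' @param se Cohort `SummarizedExperiment` (see [extractCohort()]).
#' @return `se` subset to one column per participant.
#' @export
selectBaseline <- function(se) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  ord <- order(cd$participant_id, cd$timestamp, cd$session_id)
  keep <- ord[!duplicated(cd$participant_id[ord])]
  se[, sort(keep)]
}

#' Single-pass outlier removal
#'
#' Removes values more than `k` sample standard deviations from the mean,
#' with mean and SD computed once on the full set (no re-iteration). A
#' zero-SD set is returned unchanged.
#'
#' @param values Numeric vector (NAs are dropped).
#' @param k SD multiplier (default 2).
#' @return The retained values.
#' @seealso [outlierMask()] for the positional version.
#' @export
removeOutliers <- function(values, k = 2) {
  values <- values[!is.na(values)]
  values[outlierMask(values, k)]
}

#' @rdname removeOutliers
#' @return For `outlierMask`: a logical vector, `TRUE` = retained.
#' @export
outlierMask <- function(values, k = 2) {
  if (!length(values)) return(logical(0))
  s <- stats::sd(values)
  if (is.na(s) || s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values)) <= k * s
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r with the two-sided p-value from the t transform on
#' `n - 2` degrees of freedom. Zero variance in either variable flags the
#' result as undefined rather than erroring.
#'
#' @param x,y Numeric vectors (pairwise-complete observations are used).
#' @return List with `r`, `p`, `n_used`.
#' @export
pearsonTest <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_used = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_used = n)
}

#' Correlate every feature with every clinical measure
#'
#' For each (feature, measure) pair: pairwise-complete observations are
#' taken, the single-pass 2-SD outlier rule is applied to the feature
#' values, and Pearson r and its two-sided p-value are computed. No
#' multiple-testing correction is applied by default (set `bh = TRUE` for
#' Benjamini-Hochberg adjusted significance). Pairs with zero variance or
#' fewer than 3 usable observations are returned with `NA` statistics.
#'
#' @param se Cohort `SummarizedExperiment`, normally already
#'   baseline-selected with [selectBaseline()].
#' @param alpha Significance level (default 0.05).
#' @param bh Apply Benjamini-Hochberg correction before flagging
#'   significance (default `FALSE`).
#' @param k Outlier SD multiplier (default 2).
#' @return List with `results` (data.frame: `feature`, `modality`,
#'   `measure`, `n_used`, `r`, `p`, `significant`) and `table` (the
#'   significance count matrix, modality x measure, with modality
#'   denominators as an attribute).
#' @export
correlateAll <- function(se, alpha = 0.05, bh = FALSE, k = 2) {
  mat <- SummarizedExperiment::assay(se, "features")
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  reg <- featureRegistry()
  measures <- clinicalMeasures()

  rows <- vector("list", nrow(mat) * length(measures))
  idx <- 0L
  for (f in rownames(mat)) {
    x0 <- mat[f, ]
    for (m in measures) {
      idx <- idx + 1L
      y0 <- cd[[m]]
      ok <- !is.na(x0) & !is.na(y0)
      x <- x0[ok]; y <- y0[ok]
      keep <- outlierMask(x, k)
      pt <- pearsonTest(x[keep], y[keep])
      rows[[idx]] <- data.frame(
        feature = f, modality = reg[f, "modality"], measure = m,
        n_used = pt$n_used, r = pt$r, p = pt$p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (bh) {
    res$p_adj <- stats::p.adjust(res$p, method = "BH")
    res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  } else {
    res$significant <- !is.na(res$p) & res$p < alpha
  }

  tab <- matrix(0L, 3L, length(measures),
                dimnames = list(c("visual", "audio", "text"), measures))
  sig <- res[res$significant, , drop = FALSE]
  if (nrow(sig)) {
    cnt <- table(factor(sig$modality, levels = rownames(tab)),
                 factor(sig$measure, levels = measures))
    tab[] <- as.integer(cnt)
  }
  attr(tab, "denominators") <- c(visual = 13L, audio = 28L, text = 25L)
  list(results = res, table = tab)
}
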