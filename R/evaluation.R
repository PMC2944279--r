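## ROC/AUC benchmarking of ranked search output against gold-standard
## labels: multi-query score pooling, rank-statistic AUC with the
## Hanley-McNeil standard error, and the SSM-style Q score.

#' Pool per-query labeled scores for a single ROC curve
#'
#' Combines scores from multiple queries into one list of
#' (query, entry, score, label) tuples. Self-comparisons (query id equal
#' to entry id) are excluded. Gold-standard pairs for which no score was
#' provided are assigned a value lower than the lowest provided score
#' (minimum minus 1), so that unreported comparisons rank last.
#'
#' @param scores data frame with columns \code{query_id}, \code{db_id},
#'   \code{score}.
#' @param labels data frame with columns \code{query_id}, \code{db_id},
#'   \code{label} (0/1 or logical): the gold standard, one row per
#'   (query, entry) pair to evaluate.
#' @param fillMissing logical; fill gold pairs missing from \code{scores}
#'   (otherwise they are dropped).
#' @return Data frame with columns \code{query_id}, \code{db_id},
#'   \code{score}, \code{positive}.
#' @export
poolScores <- function(scores, labels, fillMissing = TRUE) {
  stopifnot(all(c("query_id", "db_id", "score") %in% names(scores)),
            all(c("query_id", "db_id", "label") %in% names(labels)))
  key <- function(d) paste(d$query_id, d$db_id, sep = "\r")
  if (anyDuplicated(key(scores)))
    stop("duplicate (query_id, db_id) pair in scores")
  if (anyDuplicated(key(labels)))
    stop("duplicate (query_id, db_id) pair in labels")
  labels <- labels[labels$query_id != labels$db_id, , drop = FALSE]
  scores <- scores[scores$query_id != scores$db_id, , drop = FALSE]
  m <- match(key(labels), key(scores))
  s <- scores$score[m]
  if (anyNA(s)) {
    if (fillMissing) {
      if (all(is.na(s))) stop("no provided scores to derive a fill value")
      s[is.na(s)] <- min(s, na.rm = TRUE) - 1
    } else {
      keep <- !is.na(s)
      labels <- labels[keep, , drop = FALSE]
      s <- s[keep]
    }
  }
  data.frame(query_id = labels$query_id, db_id = labels$db_id,
             score = s, positive = as.logical(labels$label),
             stringsAsFactors = FALSE)
}

#' AUC with Hanley-McNeil confidence interval
#'
#' The area under the ROC curve is computed as the rank statistic
#' P(score of a positive > score of a negative) + P(tie)/2, which equals
#' the trapezoidal area under the TPR-versus-FPR curve swept over all
#' thresholds. The standard error uses the Hanley-McNeil closed form with
#' Q1 = A/(2-A) and Q2 = 2A^2/(1+A); the 95 percent interval is
#' A +/- 1.96 SE clipped to [0, 1].
#'
#' @param pooled data frame with columns \code{score} and \code{positive}
#'   (as from \code{\link{poolScores}}), or a numeric vector of scores if
#'   \code{positive} is given separately.
#' @param positive logical vector of gold labels (when \code{pooled} is a
#'   numeric vector).
#' @return A \linkS4class{ROCResult}.
#' @export
#' @examples
#' rocAuc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))  # AUC 0.75
rocAuc <- function(pooled, positive = NULL) {
  if (is.data.frame(pooled)) {
    score <- pooled$score
    positive <- pooled$positive
  } else {
    score <- pooled
  }
  positive <- as.logical(positive)
  stopifnot(length(score) == length(positive), !anyNA(score),
            !anyNA(positive))
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC undefined: need at least one positive and one negative")
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) +
                (nNeg - 1) * (q2 - auc^2)) / (nPos * nNeg))
  new("ROCResult", auc = auc, se = se,
      ciLow = max(0, auc - 1.96 * se), ciHigh = min(1, auc + 1.96 * se),
      nPos = as.integer(nPos), nNeg = as.integer(nNeg))
}

#' ROC curve points
#'
#' TPR and FPR at every score threshold, for plotting.
#'
#' @inheritParams rocAuc
#' @return Data frame with columns \code{threshold}, \code{tpr},
#'   \code{fpr}, swept from the highest score down.
#' @export
rocPoints <- function(pooled, positive = NULL) {
  if (is.data.frame(pooled)) {
    score <- pooled$score
    positive <- pooled$positive
  } else {
    score <- pooled
  }
  positive <- as.logical(positive)
  thr <- sort(unique(score), decreasing = TRUE)
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  tpr <- vapply(thr, function(t) sum(positive & score >= t) / nPos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(!positive & score >= t) / nNeg,
                numeric(1))
  data.frame(threshold = thr, tpr = tpr, fpr = fpr)
}

#' SSM-style Q score of an alignment
#'
#' Combines the number of aligned residues and their RMSD into a single
#' matching score: \code{Q = nAlign^2 / ((1 + (rmsd/3)^2) * n1 * n2)} with
#' the empirical constant R0 = 3 Angstroms. Q is 1 for a perfect
#' zero-RMSD alignment of two equal-length structures and 0 when nothing
#' aligns.
#'
#' @param nAlign number of aligned residues.
#' @param rmsd root mean square deviation of the aligned residues
#'   (Angstroms).
#' @param n1,n2 residue counts of the two structures (positive).
#' @return Numeric Q score.
#' @export
#' @examples
#' qScore(50, 3.0, 100, 100)  # 0.125
qScore <- function(nAlign, rmsd, n1, n2) {
  if (any(n1 < 1L) || any(n2 < 1L))
    stop("structure sizes must be positive")
  if (any(nAlign < 0) || any(rmsd < 0))
    stop("nAlign and rmsd must be non-negative")
  nAlign^2 / ((1 + (rmsd / 3.0)^2) * n1 * n2)
}
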