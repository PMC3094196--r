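#' @include AllClasses.R
NULL

#' Area under the ROC curve for a score against a truth set
#'
#' Rank-based AUROC (equivalent to the Mann-Whitney statistic): the
#' probability that a uniformly drawn positive outscores a uniformly drawn
#' negative, with ties counted half. Used to evaluate how well a relevance
#' ranking recovers a planted truth set.
#'
#' @param score named numeric vector.
#' @param positives character vector of names forming the truth set (or a
#'   logical vector aligned with `score`).
#' @return AUROC in \[0, 1\].
#' @export
rocAuc <- function(score, positives) {
  if (is.character(positives)) {
    stopifnot(!is.null(names(score)))
    positives <- names(score) %in% positives
  }
  stopifnot(length(positives) == length(score), is.logical(positives))
  nPos <- sum(positives)
  nNeg <- sum(!positives)
  if (nPos == 0L || nNeg == 0L)
    stop("need both positives and negatives", call. = FALSE)
  r <- rank(score)
  (sum(r[positives]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
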