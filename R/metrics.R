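#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a uniformly chosen
#' positive outranks a uniformly chosen negative, ties counted one half.
#'
#' @param scored data.frame with `score`/`label` columns, or a label vector
#'   (then `scores` must be given).
#' @param scores optional score vector.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scored, scores = NULL) {
  if (is.data.frame(scored)) { y <- scored$label; s <- scored$score }
  else { y <- scored; s <- scores }
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0L || nn == 0L)
    stop_hgt("AUROC needs both classes present (got %d positives, %d negatives)",
             np, nn, class = "hgt_metric_error")
  r <- rank(s)  # midranks handle ties as 1/2
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation over descending score thresholds; tied scores are
#' processed as one block. The no-skill baseline equals the positive
#' prevalence.
#'
#' @inheritParams auroc
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scored, scores = NULL) {
  if (is.data.frame(scored)) { y <- scored$label; s <- scored$score }
  else { y <- scored; s <- scores }
  np <- sum(y == 1)
  if (np == 0L)
    stop_hgt("AUPR needs at least one positive", class = "hgt_metric_error")
  o <- order(s, decreasing = TRUE)
  y <- y[o]; s <- s[o]
  # block boundaries: last index of each run of tied scores
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y == 1)[last]
  n_at <- last
  prec <- tp / n_at
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}
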