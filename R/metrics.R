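#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random positive
#' scores above a random negative, with ties counted half.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) truth, TRUE = positive.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both positives and negatives")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Null calibration of the Stouffer set test
#'
#' Repeatedly draws standard-normal feature scores, applies
#' [stouffer_set_test()] to a fixed-size set and records the fraction of
#' repetitions with p below `alpha` -- the empirical type-I error, which
#' should match `alpha` under the null.
#'
#' @param set_size number of member features.
#' @param n_features features per repetition.
#' @param n_reps repetitions.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return list with `rate` (empirical type-I error), `se` (binomial
#'   standard error of the nominal rate) and `n_reps`.
#' @export
stouffer_null_calibration <- function(set_size, n_features = 1000,
                                      n_reps = 1000, alpha = 0.05,
                                      seed = 1) {
  set.seed(seed)
  ids <- sprintf("f%04d", seq_len(n_features))
  members <- ids[seq_len(set_size)]
  hits <- vapply(seq_len(n_reps), function(i) {
    z <- stats::setNames(stats::rnorm(n_features), ids)
    stouffer_set_test(z, members)$p < alpha
  }, logical(1))
  list(rate = mean(hits), se = sqrt(alpha * (1 - alpha) / n_reps),
       n_reps = n_reps)
}
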