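#' Feature filter rule
#'
#' Encodes the quantification-coverage filters used for LFQ matrices: a
#' feature is retained iff its total number of quantified samples reaches
#' `min_total_quantified` AND there are at least `min_conditions` conditions
#' (adjacent in the declared time order when `adjacency_required`) each with
#' at least `min_reps_within_condition` quantified replicates.
#'
#' Presets matching common designs:
#' * phospho timecourse (16 samples): `filter_rule(4, 3, 1)`
#' * phospho inhibition (12 samples): `filter_rule(3, 3, 1)`
#' * proteome timecourse: `filter_rule(2, 2, 2, adjacency_required = TRUE)`
#' * inhibition proteome (15 samples): `filter_rule(4, 3, 1)`
#'
#' @param min_total_quantified minimum quantified values over all samples.
#' @param min_reps_within_condition minimum quantified replicates a
#'   condition needs to count.
#' @param min_conditions number of (adjacent, if required) qualifying
#'   conditions.
#' @param adjacency_required if TRUE the qualifying conditions must be
#'   consecutive in the design's declared condition order.
#' @return a `FilterRule` object.
#' @export
filter_rule <- function(min_total_quantified, min_reps_within_condition,
                        min_conditions = 1, adjacency_required = FALSE) {
  stopifnot(min_total_quantified >= 0, min_reps_within_condition >= 0,
            min_conditions >= 1)
  structure(list(min_total_quantified = min_total_quantified,
                 min_reps_within_condition = min_reps_within_condition,
                 min_conditions = min_conditions,
                 adjacency_required = adjacency_required),
            class = "FilterRule")
}

#' Filter features on quantification coverage
#'
#' @param m a `QuantMatrix`.
#' @param rule a [filter_rule()].
#' @return the `QuantMatrix` restricted to retained features.
#' @export
filter_features <- function(m, rule) {
  stopifnot(inherits(m, "QuantMatrix"), inherits(rule, "FilterRule"))
  conds <- levels(m$design$condition)
  n_reps <- max(table(m$design$condition))
  if (rule$min_reps_within_condition > n_reps)
    stop("min_reps_within_condition exceeds replicates per condition")
  obs <- !is.na(m$values)
  # quantified replicates per (feature, condition)
  per_cond <- vapply(conds, function(cc)
    rowSums(obs[, m$design$condition == cc, drop = FALSE]),
    numeric(nrow(obs)))
  if (nrow(obs) == 1) per_cond <- matrix(per_cond, nrow = 1,
                                         dimnames = list(rownames(obs), conds))
  qualifies <- per_cond >= rule$min_reps_within_condition
  if (rule$adjacency_required) {
    if (rule$min_conditions > length(conds))
      stop("min_conditions exceeds number of conditions")
    # longest run of consecutive qualifying conditions
    ok_cond <- apply(qualifies, 1, function(q) {
      r <- rle(q)
      any(r$values & r$lengths >= rule$min_conditions)
    })
  } else {
    ok_cond <- rowSums(qualifies) >= rule$min_conditions
  }
  keep <- rowSums(obs) >= rule$min_total_quantified & ok_cond
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
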