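#' Condition-specific imputation from observed replicates
#'
#' First stage of the two-stage imputation for left-censored LFQ data. For
#' every (feature, condition) cell group with at least `min_observed`
#' quantified replicates, each missing replicate is replaced by a draw from
#' `N(mean_obs, sd_obs)` of the observed replicates (a degenerate sd of 0
#' yields the mean exactly). Groups with fewer observed replicates are left
#' missing for the second stage. Observed cells are never modified.
#'
#' @param m a `QuantMatrix` on intensity scale.
#' @param min_observed minimum observed replicates for a condition to be
#'   imputable (default 3, i.e. "more than two").
#' @param method `"draw"` (seeded normal draw) or `"mean"` (deterministic).
#' @param seed integer seed.
#' @return partially imputed `QuantMatrix`.
#' @export
impute_condition_specific <- function(m, min_observed = 3,
                                      method = c("draw", "mean"), seed = 1) {
  stopifnot(inherits(m, "QuantMatrix"))
  if (m$scale != "intensity") stop("imputation expects intensity scale")
  method <- match.arg(method)
  set.seed(seed)
  vals <- m$values
  for (cc in levels(m$design$condition)) {
    cols <- which(m$design$condition == cc)
    sub <- vals[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    n_mis <- rowSums(is.na(sub))
    rows <- which(n_obs >= min_observed & n_mis > 0)
    for (r in rows) {
      x <- sub[r, ]
      mu <- mean(x, na.rm = TRUE)
      sdev <- stats::sd(x, na.rm = TRUE)
      miss <- which(is.na(x))
      imp <- if (method == "mean" || sdev == 0) rep(mu, length(miss))
             else stats::rnorm(length(miss), mu, sdev)
      vals[r, cols[miss]] <- imp
    }
  }
  out <- m
  out$values <- vals
  out
}

#' Random-tail (down-shifted normal) imputation
#'
#' Second stage: models intensity-dependent (left-censored) missingness.
#' Every remaining missing cell in sample `s` is drawn from
#' `N(mean_s - shift * sd_s, (width * sd_s)^2)` where `mean_s` and `sd_s`
#' are computed over the observed cells of that sample (or of the whole
#' matrix when `per_sample = FALSE`). No missing cells remain afterwards.
#'
#' @param m a `QuantMatrix` on intensity scale.
#' @param shift down-shift in sample sds (default 1.8).
#' @param width width of the imputation distribution in sample sds
#'   (default 0.3).
#' @param per_sample compute the moments per sample (default) or globally.
#' @param seed integer seed.
#' @return fully imputed `QuantMatrix`.
#' @export
impute_random_tail <- function(m, shift = 1.8, width = 0.3,
                               per_sample = TRUE, seed = 1) {
  stopifnot(inherits(m, "QuantMatrix"))
  if (m$scale != "intensity") stop("imputation expects intensity scale")
  set.seed(seed + 1L)
  vals <- m$values
  if (!anyNA(vals)) return(m)
  if (per_sample) {
    for (s in seq_len(ncol(vals))) {
      x <- vals[, s]
      miss <- which(is.na(x))
      if (length(miss) == 0) next
      obs <- x[!is.na(x)]
      if (length(obs) < 2)
        stop(sprintf("sample '%s' has fewer than 2 observed values; sd undefined",
                     colnames(vals)[s]))
      vals[miss, s] <- stats::rnorm(length(miss),
                                    mean(obs) - shift * stats::sd(obs),
                                    width * stats::sd(obs))
    }
  } else {
    obs <- vals[!is.na(vals)]
    if (length(obs) < 2) stop("fewer than 2 observed values; sd undefined")
    miss <- which(is.na(vals))
    vals[miss] <- stats::rnorm(length(miss),
                               mean(obs) - shift * stats::sd(obs),
                               width * stats::sd(obs))
  }
  out <- m
  out$values <- vals
  out
}
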