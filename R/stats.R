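#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps `stats::p.adjust(method = "BH")` after
#' validating the input range).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classical one-way ANOVA for a single feature
#'
#' Equal-variance one-way F-test across condition groups. A degenerate fit
#' (zero within-group variance with non-zero between-group variance) is
#' reported as `F = Inf`, `p = 0` with `degenerate = TRUE`.
#'
#' @param values numeric vector of replicate-level values.
#' @param groups condition labels, same length.
#' @return list with `F`, `p`, `degenerate`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 replicates each")
  # anova.lm warns on an essentially perfect fit; that case is handled
  # explicitly below via the degenerate flag
  a <- suppressWarnings(stats::anova(stats::lm(values ~ groups)))
  Fv <- a[["F value"]][1]
  p <- a[["Pr(>F)"]][1]
  degenerate <- FALSE
  if (a[["Mean Sq"]][2] <= .Machine$double.eps * mean(values)^2 &&
      a[["Mean Sq"]][1] > 0) {
    Fv <- Inf; p <- 0; degenerate <- TRUE
  }
  list(F = Fv, p = p, degenerate = degenerate)
}

#' Call dynamically regulated features from a time-course ratio matrix
#'
#' A feature is dynamic when its absolute mean log2 fold change (relative to
#' the reference) exceeds `fc_threshold` in at least `min_timepoints` time
#' points AND its one-way ANOVA across all profiled conditions reaches a BH
#' q-value of `fdr` or smaller.
#'
#' @param ratios ratio-scale `QuantMatrix` (reference condition ratios ~ 0).
#' @param reference reference condition label (defaults to the matrix's
#'   recorded reference).
#' @param fc_threshold |log2 FC| threshold, exceeded strictly.
#' @param min_timepoints minimum number of time points above the threshold.
#' @param fdr BH q cutoff (inclusive).
#' @return data.frame: feature, max_abs_fc, n_big_fc, F, p, q, dynamic.
#' @export
dynamic_call <- function(ratios, reference = attr(ratios, "reference"),
                         fc_threshold = 1, min_timepoints = 2, fdr = 0.05) {
  stopifnot(inherits(ratios, "QuantMatrix"), ratios$scale == "ratio")
  conds <- levels(ratios$design$condition)
  non_ref <- setdiff(conds, reference)
  fc <- vapply(non_ref, function(cc)
    rowMeans(ratios$values[, ratios$design$condition == cc, drop = FALSE]),
    numeric(nrow(ratios$values)))
  if (nrow(ratios$values) == 1) fc <- matrix(fc, nrow = 1)
  n_big <- rowSums(abs(fc) > fc_threshold)
  groups <- ratios$design$condition
  ap <- apply(ratios$values, 1, function(x) {
    r <- anova_oneway(x, groups)
    c(r$F, r$p)
  })
  q <- bh_adjust(ap[2, ])
  data.frame(feature = rownames(ratios$values),
             max_abs_fc = apply(abs(fc), 1, max),
             n_big_fc = n_big, F = ap[1, ], p = ap[2, ], q = q,
             dynamic = n_big >= min_timepoints & q <= fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Inverse of the trigamma function
#'
#' Newton iteration solving `trigamma(x) = y`, used by the empirical-Bayes
#' moment estimator.
#'
#' @param y positive target value.
#' @return x with `trigamma(x) = y` (to ~1e-8).
#' @export
trigamma_inverse <- function(y) {
  stopifnot(y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moments of a variance prior
#'
#' Fits the scaled inverse chi-square prior (`s0^2`, `d0`) of per-feature
#' variances by the method of moments on `log(s2)`: with
#' `e = log(s2) - digamma(d/2) + log(d/2)`, the excess of `var(e)` over
#' `trigamma(d/2)` determines `d0` through the trigamma inverse, and
#' `mean(e)` then determines `s0^2`. When the empirical variance of
#' `log(s2)` is at or below the sampling floor, `d0 = Inf` (all variances
#' shrink to the common `s0^2`).
#'
#' @param s2 per-feature sample variances (>= 10 positive values).
#' @param d residual degrees of freedom of each `s2`.
#' @return list with `s02` and `d0` (possibly `Inf`).
#' @export
eb_moderate <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10) stop("need >= 10 features with positive variance")
  s2 <- s2[ok]
  if (stats::var(log(s2)) == 0)
    return(list(s02 = s2[1], d0 = Inf))
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  list(s02 = s02, d0 = d0)
}

#' Moderated t-test from summary statistics
#'
#' Shrinks each feature's variance toward the EB prior,
#' `s2_post = (d0 * s02 + d * s2) / (d0 + d)`, and tests
#' `t = log2FC / sqrt(s2_post * (1/n1 + 1/n2))` on `d + d0` degrees of
#' freedom (standard normal when `d0 = Inf`). `d0 = 0` reproduces the
#' ordinary pooled t-test exactly. A feature is called DE when
#' `|log2FC| >= fc_threshold` and `q < fdr` (FC inclusive, q strict).
#'
#' @param fc named per-feature log2 fold changes.
#' @param s2 per-feature pooled sample variances.
#' @param n1,n2 group sizes.
#' @param s02,d0 EB prior variance and df (see [eb_moderate()]).
#' @param fc_threshold,fdr DE call thresholds.
#' @return data.frame: feature, log2FC, s2, s2_post, t, df_total, p, q, de.
#' @export
moderated_t <- function(fc, s2, n1, n2, s02, d0, fc_threshold = 1,
                        fdr = 0.05) {
  d <- n1 + n2 - 2
  stopifnot(d >= 1, d0 >= 0)
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- fc / se
  df_total <- d + d0
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t))
       else 2 * stats::pt(-abs(t), df_total)
  q <- bh_adjust(p)
  data.frame(feature = if (is.null(names(fc))) seq_along(fc) else names(fc),
             log2FC = fc, s2 = s2, s2_post = s2_post, t = t,
             df_total = df_total, p = p, q = q,
             de = abs(fc) >= fc_threshold & q < fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-group moderated differential test on matrices
#'
#' Convenience wrapper: pooled per-feature variances, EB shrinkage via
#' [eb_moderate()] (or a forced `d0`), then [moderated_t()].
#'
#' @param x1,x2 features x replicates matrices of the two groups (same
#'   features, same order).
#' @param d0 optional override of the prior df (`0` = ordinary t).
#' @param fc_threshold,fdr DE call thresholds.
#' @return a [moderated_t()] table.
#' @export
two_group_de <- function(x1, x2, d0 = NULL, fc_threshold = 1, fdr = 0.05) {
  stopifnot(nrow(x1) == nrow(x2))
  n1 <- ncol(x1); n2 <- ncol(x2)
  fc <- rowMeans(x1) - rowMeans(x2)
  v1 <- apply(x1, 1, stats::var)
  v2 <- apply(x2, 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (is.null(d0)) {
    eb <- eb_moderate(s2, n1 + n2 - 2)
    s02 <- eb$s02; d0 <- eb$d0
  } else {
    s02 <- if (d0 == 0) 0 else mean(s2)
  }
  moderated_t(stats::setNames(fc, rownames(x1)), s2, n1, n2, s02, d0,
              fc_threshold, fdr)
}

#' Two-stage overexpression contrast against a shared reference
#'
#' Both treatment conditions are first converted to per-replicate ratios
#' against the mean of the shared reference condition, then the two ratio
#' sets are compared with the moderated t-test. Used for
#' wild-type-vs-mutant overexpression designs normalized to a common
#' control.
#'
#' @param m intensity- or ratio-scale `QuantMatrix` holding all three
#'   conditions.
#' @param treatment,mutant the two condition labels to compare.
#' @param reference the shared reference condition label.
#' @param ... passed to [two_group_de()].
#' @return a [moderated_t()] table for treatment vs mutant.
#' @export
contrast_vs_reference_de <- function(m, treatment, mutant, reference, ...) {
  stopifnot(inherits(m, "QuantMatrix"))
  conds <- levels(m$design$condition)
  if (!all(c(treatment, mutant, reference) %in% conds))
    stop("conditions not all present in design")
  ref_mean <- rowMeans(m$values[, m$design$condition == reference,
                                drop = FALSE])
  r1 <- m$values[, m$design$condition == treatment, drop = FALSE] - ref_mean
  r2 <- m$values[, m$design$condition == mutant, drop = FALSE] - ref_mean
  two_group_de(r1, r2, ...)
}
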