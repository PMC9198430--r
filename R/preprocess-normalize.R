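#' Convert intensities to log2 ratios relative to a reference condition
#'
#' Each value becomes the value minus the feature's mean over the reference
#' condition replicates of the same batch, so reference structure cannot
#' re-introduce batch effects. Reference-sample column means per feature
#' become 0 (exactly, when a batch has a single reference mean).
#'
#' @param m fully imputed `QuantMatrix` on intensity scale.
#' @param reference_condition label of the reference (e.g. `"0h"` or
#'   `"ctrl"`).
#' @return `QuantMatrix` on ratio scale.
#' @export
to_ratios <- function(m, reference_condition) {
  stopifnot(inherits(m, "QuantMatrix"))
  if (anyNA(m$values)) stop("to_ratios requires a fully imputed matrix")
  if (!reference_condition %in% levels(m$design$condition))
    stop("reference condition not present: ", reference_condition)
  vals <- m$values
  for (b in unique(m$design$batch)) {
    in_b <- m$design$batch == b
    ref_cols <- which(in_b & m$design$condition == reference_condition)
    if (length(ref_cols) == 0)
      stop(sprintf("batch '%s' has no samples of reference condition '%s'",
                   b, reference_condition))
    ref_mean <- rowMeans(m$values[, ref_cols, drop = FALSE])
    vals[, which(in_b)] <- m$values[, which(in_b), drop = FALSE] - ref_mean
  }
  out <- m
  out$values <- vals
  out$scale <- "ratio"
  attr(out, "reference") <- reference_condition
  out
}

#' Remove additive batch effects
#'
#' Location-only batch correction. `center` subtracts, per feature, each
#' batch mean's deviation from the feature's grand mean. `eb_location`
#' shrinks those deviations toward 0 with an empirical-Bayes weight
#' `n_b * tau2 / (n_b * tau2 + sigma2)` before subtracting, where `sigma2`
#' is the feature's within-batch residual variance and `tau2` is a
#' method-of-moments estimate of the between-batch deviation variance
#' pooled across features.
#'
#' @param m a `QuantMatrix` (usually ratio scale).
#' @param method `"center"` or `"eb_location"`.
#' @return batch-corrected `QuantMatrix`.
#' @export
correct_batch <- function(m, method = c("center", "eb_location")) {
  stopifnot(inherits(m, "QuantMatrix"))
  method <- match.arg(method)
  batches <- unique(m$design$batch)
  if (length(batches) < 2) {
    warning("single batch; batch correction is a no-op")
    return(m)
  }
  vals <- m$values
  grand <- rowMeans(vals)
  dev <- vapply(batches, function(b)
    rowMeans(vals[, m$design$batch == b, drop = FALSE]) - grand,
    numeric(nrow(vals)))
  if (nrow(vals) == 1) dev <- matrix(dev, nrow = 1)
  n_b <- vapply(batches, function(b) sum(m$design$batch == b), numeric(1))
  if (method == "eb_location") {
    # within-batch residual variance per feature
    sigma2 <- rep(0, nrow(vals))
    df <- 0
    for (b in batches) {
      sub <- vals[, m$design$batch == b, drop = FALSE]
      sigma2 <- sigma2 + rowSums((sub - rowMeans(sub))^2)
      df <- df + ncol(sub) - 1
    }
    sigma2 <- sigma2 / max(df, 1)
    # method of moments across features: E[dev^2] = tau2 + sigma2/n_b
    tau2 <- max(0, mean(sweep(dev^2, 2, mean(sigma2) / n_b, "-")))
    w <- sweep(matrix(tau2 * n_b, nrow(vals), length(batches),
                      byrow = TRUE), 1, sigma2, function(a, s) a / (a + s))
    w[!is.finite(w)] <- 1
    dev <- dev * w
  }
  colnames(dev) <- batches
  for (b in batches)
    vals[, m$design$batch == b] <- vals[, m$design$batch == b, drop = FALSE] -
      dev[, b]
  out <- m
  out$values <- vals
  out
}

#' Select stable features as negative controls
#'
#' Ranks features by the variance of their condition means (ascending) and
#' returns the `n` most stable; ties are broken by total variance, then by
#' feature id, for determinism. Intended to provide the control set for
#' [ruv_normalize()], emulating "stably expressed genes as negative
#' controls".
#'
#' @param m a ratio-scale `QuantMatrix`.
#' @param n number of features to return.
#' @return character vector of feature ids.
#' @export
select_stable_features <- function(m, n) {
  stopifnot(inherits(m, "QuantMatrix"))
  conds <- levels(m$design$condition)
  cm <- vapply(conds, function(cc)
    rowMeans(m$values[, m$design$condition == cc, drop = FALSE]),
    numeric(nrow(m$values)))
  if (nrow(m$values) == 1) cm <- matrix(cm, nrow = 1)
  v_cond <- apply(cm, 1, stats::var)
  v_tot <- apply(m$values, 1, stats::var)
  ord <- order(v_cond, v_tot, rownames(m$values))
  rownames(m$values)[ord[seq_len(min(n, nrow(m$values)))]]
}

#' Remove unwanted variation using negative-control features
#'
#' Estimates `k` unwanted sample-space factors as the top right singular
#' vectors of the row-centered controls submatrix, regresses every feature
#' on them and removes the fitted component (feature means preserved).
#'
#' @param m a `QuantMatrix`.
#' @param controls feature ids assumed unaffected by the biology.
#' @param k number of unwanted factors, `1 <= k < n_samples`.
#' @return corrected `QuantMatrix`.
#' @export
ruv_normalize <- function(m, controls, k = 1) {
  stopifnot(inherits(m, "QuantMatrix"))
  missing_ctrl <- setdiff(controls, rownames(m$values))
  if (length(missing_ctrl) > 0)
    stop("controls not in matrix: ", paste(missing_ctrl, collapse = ", "))
  if (k < 1 || k >= ncol(m$values))
    stop("k must satisfy 1 <= k < n_samples")
  ctrl <- m$values[controls, , drop = FALSE]
  ctrl <- ctrl - rowMeans(ctrl)
  sv <- svd(ctrl)
  rank <- sum(sv$d > max(dim(ctrl)) * .Machine$double.eps * sv$d[1])
  if (k >= rank && rank < min(dim(ctrl)))
    stop(sprintf("k = %d not below the rank (%d) of the controls submatrix",
                 k, rank))
  W <- sv$v[, seq_len(k), drop = FALSE]            # samples x k
  Y <- m$values
  mu <- rowMeans(Y)
  Yc <- Y - mu
  # per-feature OLS on orthonormal W: coef = Yc W
  fitted <- (Yc %*% W) %*% t(W)
  out <- m
  out$values <- Yc - fitted + mu
  out
}

#' Correct phosphosite ratios by the host protein's proteome ratios
#'
#' Subtracts, from each site's ratio, the host protein's mean ratio at the
#' matching condition, so phosphorylation changes are read net of protein
#' abundance changes. Sites whose protein is absent from the proteome pass
#' through unchanged and are flagged.
#'
#' @param phospho_ratios ratio-scale `QuantMatrix` of sites.
#' @param protein_ratios ratio-scale `QuantMatrix` of proteins.
#' @param site2protein named character vector mapping site id -> protein id.
#' @return corrected `QuantMatrix` with attribute `unmapped` (site ids left
#'   uncorrected).
#' @export
proteome_correct <- function(phospho_ratios, protein_ratios, site2protein) {
  stopifnot(inherits(phospho_ratios, "QuantMatrix"),
            inherits(protein_ratios, "QuantMatrix"))
  if (phospho_ratios$scale != "ratio" || protein_ratios$scale != "ratio")
    stop("both matrices must be on ratio scale")
  conds <- as.character(phospho_ratios$design$condition)
  pconds <- unique(as.character(protein_ratios$design$condition))
  absent <- setdiff(unique(conds), pconds)
  if (length(absent) > 0)
    stop("condition(s) absent from protein data: ",
         paste(absent, collapse = ", "))
  pmean <- vapply(pconds, function(cc)
    rowMeans(protein_ratios$values[, protein_ratios$design$condition == cc,
                                   drop = FALSE]),
    numeric(nrow(protein_ratios$values)))
  if (nrow(protein_ratios$values) == 1)
    pmean <- matrix(pmean, nrow = 1, dimnames = list(NULL, pconds))
  rownames(pmean) <- rownames(protein_ratios$values)
  sites <- rownames(phospho_ratios$values)
  prot <- site2protein[sites]
  mapped <- !is.na(prot) & prot %in% rownames(pmean)
  vals <- phospho_ratios$values
  if (any(mapped)) {
    corr <- pmean[prot[mapped], conds, drop = FALSE]
    vals[mapped, ] <- vals[mapped, , drop = FALSE] - corr
  }
  out <- phospho_ratios
  out$values <- vals
  attr(out, "unmapped") <- sites[!mapped]
  out
}
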