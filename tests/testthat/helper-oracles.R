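# Independent oracles and small fixture builders used across test files.

# Brute-force BH step-up straight from the definition:
# q_(i) = min_{j >= i} min(1, n * p_(j) / j), mapped back to input order.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(n)
  for (i in seq_len(n)) {
    best <- 1
    for (j in i:n) best <- min(best, n * ps[j] / j)
    qs[i] <- best
  }
  out <- numeric(n)
  out[o] <- qs
  out
}

# Textbook one-way ANOVA F from the sum-of-squares decomposition.
textbook_f <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}

# Kullback-Leibler divergence of a residue distribution from uniform(20).
kl_uniform <- function(p) {
  p <- p[p > 0]
  sum(p * log(p / (1 / 20)))
}

# Build a QuantMatrix from a plain matrix and a condition x replicate layout.
toy_quant <- function(values, conditions, n_reps, n_batches = 1,
                      scale = "intensity") {
  design <- make_design(conditions, n_replicates = n_reps,
                        n_batches = n_batches)
  design <- design[seq_len(ncol(values)), , drop = FALSE]
  colnames(values) <- design$sample
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  quant_matrix(values, design, scale = scale)
}

# All permutations of 1:n as rows of a matrix (n! x n).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# Mean per-position KL from uniform of a PSSM, skipping the fixed centre.
pssm_information <- function(pssm) {
  centre <- (nrow(pssm) + 1) / 2
  mean(apply(pssm[-centre, , drop = FALSE], 1, kl_uniform))
}
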