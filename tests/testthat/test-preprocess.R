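conds4 <- c("0h", "30m", "24h", "d5")

# builds a features x (conditions x reps) observation pattern: `pattern` is a
# list of per-condition observed counts per feature
pattern_matrix <- function(pattern, conditions, n_reps, n_batches = 1) {
  vals <- matrix(NA_real_, length(pattern), length(conditions) * n_reps)
  for (f in seq_along(pattern)) {
    for (ci in seq_along(conditions)) {
      k <- pattern[[f]][ci]
      if (k > 0)
        vals[f, (ci - 1) * n_reps + seq_len(k)] <- 20 + f + ci
    }
  }
  # samples of make_design are ordered condition-major, replicate-minor
  toy_quant(vals, conditions, n_reps, n_batches)
}

test_that("coverage filters retain and drop exactly as specified", {
  # phospho timecourse: >= 4 of 16 total AND >= 3 of 4 in some time point
  m <- pattern_matrix(list(c(3, 0, 0, 0),    # total 3 -> dropped
                           c(3, 1, 0, 0),    # total 4, one cond 3/4 -> kept
                           c(2, 2, 0, 0),    # total 4, no cond with 3 -> drop
                           c(4, 4, 4, 4)),   # complete -> kept
                      conds4, 4)
  kept <- rownames(filter_features(m, filter_rule(4, 3, 1))$values)
  expect_identical(kept, c("f002", "f004"))

  # proteome: >= 2 of 4 replicates in >= 2 adjacent time points
  m2 <- pattern_matrix(list(c(2, 0, 2, 0),   # t1 and t3: not adjacent -> drop
                            c(2, 2, 0, 0),   # t1 and t2: adjacent -> kept
                            c(0, 2, 2, 2)),  # run of 3 -> kept
                       conds4, 4)
  kept2 <- rownames(filter_features(
    m2, filter_rule(4, 2, 2, adjacency_required = TRUE))$values)
  expect_identical(kept2, c("f002", "f003"))

  # phospho inhibition: >= 3 of 12 total AND >= 3 of 4 in some condition
  m3 <- pattern_matrix(list(c(3, 0, 0),      # kept: total 3, cond with 3
                            c(2, 1, 0)),     # dropped: no condition with 3
                       c("ctrl", "PD", "SP"), 4)
  kept3 <- rownames(filter_features(m3, filter_rule(3, 3, 1))$values)
  expect_identical(kept3, "f001")

  # inhibition proteome: >= 4 of 15 total AND >= 3 of 4 in some condition
  vals <- matrix(NA_real_, 3, 15)
  vals[1, 1:3] <- 21; vals[1, 5] <- 22        # total 4, cond1 3/4 -> kept
  vals[2, c(1, 2, 5, 6)] <- 21                # total 4, max 2 per cond -> drop
  vals[3, 1:3] <- 21                          # total 3 -> drop
  rownames(vals) <- sprintf("f%03d", 1:3)
  design <- make_design(c("c1", "c2", "c3", "c4"), 4, 1)[1:15, ]
  colnames(vals) <- design$sample
  m4 <- quant_matrix(vals, design)
  kept4 <- rownames(filter_features(m4, filter_rule(4, 3, 1))$values)
  expect_identical(kept4, "f001")
})

test_that("filtering is monotone in every threshold", {
  set.seed(21)
  for (rep in 1:5) {
    vals <- matrix(rnorm(30 * 16, 25), 30, 16)
    vals[runif(length(vals)) < 0.5] <- NA
    m <- toy_quant(vals, conds4, 4)
    strict <- rownames(filter_features(m, filter_rule(6, 3, 2))$values)
    for (rule in list(filter_rule(5, 3, 2), filter_rule(6, 2, 2),
                      filter_rule(6, 3, 1)))
      expect_true(all(strict %in%
                        rownames(filter_features(m, rule)$values)))
  }
})

test_that("condition-specific imputation follows the observed moments", {
  vals <- matrix(NA_real_, 3, 16)
  vals[1, 1:3] <- c(5, 6, 7)      # 3 observed -> imputable
  vals[2, 1:2] <- c(5, 6)         # 2 observed -> untouched
  vals[3, 1:3] <- 6               # sd 0 -> imputed with the mean exactly
  vals[, 5:16] <- 10              # keep other conditions complete
  m <- toy_quant(vals, conds4, 4)
  out <- impute_condition_specific(m, seed = 3)
  expect_true(is.finite(out$values[1, 4]))
  expect_true(is.na(out$values[2, 3]) && is.na(out$values[2, 4]))
  expect_identical(out$values[3, 4], 6)
  # observed cells bit-identical
  obs <- !is.na(m$values)
  expect_identical(out$values[obs], m$values[obs])

  # Monte-Carlo contract: draws come from N(mean_obs, sd_obs)
  draws <- vapply(1:1000, function(i)
    impute_condition_specific(m, seed = i)$values[1, 4], numeric(1))
  expect_lt(abs(mean(draws) - 6), 0.1)
  expect_lt(abs(sd(draws) - 1), 0.15)
})

test_that("random-tail imputation matches the down-shifted normal", {
  # degenerate width: imputed values collapse onto mean_s - shift * sd_s
  vals <- matrix(c(10, 12, NA, 14, 10, 12, 13, 14), 4, 2)
  m <- toy_quant(vals, c("a", "b"), 2)
  out <- impute_random_tail(m, shift = 0, width = 1e-9, seed = 1)
  expect_equal(out$values[3, 1], mean(c(10, 12, 14)), tolerance = 1e-6)

  # large-sample mean of the imputed tail
  set.seed(5)
  big <- matrix(NA_real_, 12000, 2)
  big[, 2] <- rnorm(12000, 20, 2)
  big[1:2000, 1] <- rnorm(2000, 20, 2)
  mbig <- toy_quant(big, c("a", "b"), 1)
  obs <- big[1:2000, 1]
  outb <- impute_random_tail(mbig, seed = 2)
  imputed <- outb$values[2001:12000, 1]
  expect_lt(abs(mean(imputed) - (mean(obs) - 1.8 * sd(obs))), 0.05 * sd(obs))
  expect_equal(n_missing(outb), 0L)
  # observed cells bit-identical
  keep <- !is.na(big)
  expect_identical(outb$values[keep], big[keep])

  # no-missing matrix returned unchanged; tiny samples rejected
  full <- toy_quant(matrix(1:8 + 0.5, 4, 2), c("a", "b"), 1)
  expect_identical(impute_random_tail(full, seed = 1)$values, full$values)
  one_obs <- toy_quant(matrix(c(1, NA, NA, NA), 2, 2), c("a", "b"), 1)
  expect_error(impute_random_tail(one_obs), "fewer than 2 observed")
})

test_that("ratio conversion centers on the per-batch reference mean", {
  vals <- matrix(10, 2, 8)
  # samples: 0h_r1..r4 (batches A,A,B,B), 30m_r1..r4 (A,A,B,B)
  vals[1, ] <- c(10, 10, 10, 10, 12, 13, 11, 12)  # ref mean 10 in each batch
  m <- toy_quant(vals, c("0h", "30m"), 4, n_batches = 2)
  r <- to_ratios(m, "0h")
  expect_equal(r$values[2, ], setNames(rep(0, 8), colnames(r$values)))
  expect_equal(unname(r$values[1, 5]), 2)
  ref_cols <- r$design$condition == "0h"
  expect_equal(rowMeans(r$values[, ref_cols]), c(f001 = 0, f002 = 0))
  expect_identical(r$scale, "ratio")

  m_nobatch <- m
  m_nobatch$design$batch[1:2] <- "B"  # batch A loses its reference samples
  expect_error(to_ratios(m_nobatch, "0h"), "batch")
})

test_that("batch correction removes planted location shifts", {
  set.seed(8)
  design <- make_design(conds4, 4, 2)
  base <- matrix(rnorm(50 * 16, 0, 1), 50, 16)
  delta <- rnorm(50, 0, 2)
  shifted <- base + outer(delta, as.numeric(design$batch == "B"))
  rownames(shifted) <- sprintf("f%03d", 1:50)
  colnames(shifted) <- design$sample
  m <- quant_matrix(shifted, design, scale = "ratio")
  for (method in c("center", "eb_location")) {
    out <- correct_batch(m, method)
    gap <- rowMeans(out$values[, out$design$batch == "A"]) -
      rowMeans(out$values[, out$design$batch == "B"])
    gap0 <- rowMeans(m$values[, m$design$batch == "A"]) -
      rowMeans(m$values[, m$design$batch == "B"])
    if (method == "center") expect_equal(max(abs(gap)), 0, tolerance = 1e-12)
    expect_lt(median(abs(gap)), median(abs(gap0)))
    # batch F statistic drops
    f_pre <- apply(m$values, 1, function(x)
      anova_oneway(x, m$design$batch)$F)
    f_post <- apply(out$values, 1, function(x)
      anova_oneway(x, out$design$batch)$F)
    expect_lt(median(f_post), median(f_pre))
  }
  single <- m
  single$design$batch <- "A"
  expect_warning(correct_batch(single), "single batch")
})

test_that("shift invariance: per-sample constants vanish after centering", {
  set.seed(9)
  design <- make_design(c("0h", "30m"), 4, 2)
  vals <- matrix(rnorm(20 * 8, 25), 20, 8,
                 dimnames = list(sprintf("f%02d", 1:20), design$sample))
  m <- quant_matrix(vals, design)
  shift <- ifelse(design$batch == "B", 1.7, 0)
  m2 <- m
  m2$values <- sweep(vals, 2, shift, "+")
  a <- correct_batch(to_ratios(m, "0h"), "center")
  b <- correct_batch(to_ratios(m2, "0h"), "center")
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("stable-feature selection prefers flat, background features", {
  set.seed(10)
  design <- make_design(conds4, 4, 1)
  vals <- rbind(matrix(rnorm(10 * 16, 0, 1) +
                         rep(rnorm(10, 0, 3), 16), 10, 16),
                matrix(0, 1, 16),
                matrix(rnorm(9 * 16, 0, 0.5), 9, 16))
  # give the varying features condition structure
  vals[1:10, design$condition == "24h"] <- vals[1:10, design$condition == "24h"] + 4
  rownames(vals) <- sprintf("f%02d", 1:20)
  colnames(vals) <- design$sample
  m <- quant_matrix(vals, design, scale = "ratio")
  expect_identical(select_stable_features(m, 1), "f11")  # the constant one
  expect_length(select_stable_features(m, 20), 20L)
  expect_length(select_stable_features(m, 99), 20L)

  # on simulated data most selected controls are true background
  sc <- run_timecourse_scenario(seed = 3, ruv_k = 0)
  controls <- select_stable_features(sc$norm, 30)
  frac_bg <- mean(is.na(sc$sim$truth$site2kinase[controls]))
  expect_gte(frac_bg, 0.8)
})

test_that("RUV removes a planted unwanted factor from the controls", {
  set.seed(12)
  n_s <- 10
  w <- rnorm(n_s)
  gamma <- c(rnorm(10, 0, 2), rep(0, 20))   # only controls load on w
  signal <- rbind(matrix(0, 10, n_s),
                  matrix(rnorm(20 * n_s, 0, 1), 20, n_s))
  Y <- outer(gamma, w) + signal + matrix(rnorm(30 * n_s, 0, 0.01), 30, n_s)
  rownames(Y) <- sprintf("f%02d", 1:30)
  design <- make_design(c("a", "b"), 5, 1)
  colnames(Y) <- design$sample
  m <- quant_matrix(Y, design, scale = "ratio")
  controls <- sprintf("f%02d", 1:10)
  out <- ruv_normalize(m, controls, k = 1)
  for (f in controls)
    expect_lt(abs(cor(out$values[f, ], w)), 0.1)
  expect_error(ruv_normalize(m, controls, k = 0), "k must")
  expect_error(ruv_normalize(m, controls, k = n_s), "k must")

  # idempotence: once the unwanted factor is gone (every feature loads on
  # w, negligible residual), a second pass is a numerical no-op
  gamma_all <- rnorm(30, 0, 2)
  Y2 <- outer(gamma_all, w) + matrix(rnorm(30 * n_s, 0, 1e-9), 30, n_s) + 25
  dimnames(Y2) <- dimnames(Y)
  m2 <- quant_matrix(Y2, design, scale = "ratio")
  once <- ruv_normalize(m2, controls, k = 1)
  twice <- ruv_normalize(once, controls, k = 1)
  expect_lt(max(abs(twice$values - once$values)), 1e-8)
})

test_that("proteome correction subtracts host-protein condition means", {
  design <- make_design(c("0h", "24h"), 2, 1)
  site_vals <- matrix(c(0, 0, 3, 3,
                        0, 0, 2, 2), 2, 4, byrow = TRUE,
                      dimnames = list(c("P1_S10", "PX_S5"), design$sample))
  prot_vals <- matrix(c(0, 0, 1, 1), 1, 4,
                      dimnames = list("P1", design$sample))
  ph <- quant_matrix(site_vals, design, scale = "ratio")
  pr <- quant_matrix(prot_vals, design, scale = "ratio")
  map <- c(P1_S10 = "P1", PX_S5 = "PX")
  out <- proteome_correct(ph, pr, map)
  expect_equal(unname(out$values["P1_S10", 3]), 2)   # 3 - 1
  expect_equal(unname(out$values["PX_S5", 3]), 2)    # unmapped: unchanged
  expect_identical(attr(out, "unmapped"), "PX_S5")

  # zero protein ratios: identity
  pr0 <- pr; pr0$values[] <- 0
  expect_equal(proteome_correct(ph, pr0, map)$values, ph$values)
  # a site tracking its protein cancels to ~0
  pr_eq <- pr; pr_eq$values[1, ] <- site_vals[1, ]
  expect_equal(unname(proteome_correct(ph, pr_eq, map)$values["P1_S10", ]),
               rep(0, 4))
  # missing condition in the protein data
  pr_bad <- quant_matrix(prot_vals[, 1:2, drop = FALSE],
                         design[1:2, ], scale = "ratio")
  expect_error(proteome_correct(ph, pr_bad, map), "24h")
})
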