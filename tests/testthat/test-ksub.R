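test_that("PSSM estimation follows the pseudocount closed form", {
  w <- "AAAAAAASAAAAAAA"
  p <- build_pssm(rep(w, 6), alpha = 0.01, min_known = 5)
  expect_equal(unname(p$prob[1, "A"]), (6 + 0.01) / (6 + 0.2))
  expect_equal(unname(p$prob[8, "S"]), (6 + 0.01) / (6 + 0.2))
  expect_equal(unname(p$prob[1, "C"]), 0.01 / 6.2)
  expect_true(all(abs(rowSums(p$prob) - 1) < 1e-9))

  # alpha -> infinity limit: rows tend to uniform
  p_inf <- build_pssm(rep(w, 6), alpha = 1e9)
  expect_lt(max(abs(p_inf$prob - 1 / 20)), 1e-6)

  # padding excluded position-wise
  wins <- c("-AAASAAA", "-AAASAAA", "CAAASAAA", "CAAASAAA", "CAAASAAA")
  pp <- build_pssm(wins, alpha = 0.01, min_known = 5)
  expect_equal(unname(pp$prob[1, "C"]), (3 + 0.01) / (3 + 0.2))

  expect_error(build_pssm(rep(w, 4), min_known = 5), "at least 5")

  # frequencies of a large sample from a known PSSM are recovered
  truth <- make_kinase_models(1, motif_informativeness = 0.5,
                              seed = 2)[[1]]$pssm
  set.seed(2)
  est <- build_pssm(sample_windows(truth, 1000), alpha = 0.01)
  expect_lt(max(abs(est$prob - truth)), 0.03)
})

test_that("motif score is min-max normalized over achievable windows", {
  wins <- sample_windows(make_kinase_models(1, motif_informativeness = 0.8,
                                            seed = 15)[[1]]$pssm, 30)
  p <- build_pssm(wins)
  argmax <- paste(colnames(p$prob)[apply(p$prob, 1, which.max)],
                  collapse = "")
  argmin <- paste(colnames(p$prob)[apply(p$prob, 1, which.min)],
                  collapse = "")
  expect_equal(motif_score(p, argmax), 1)
  expect_equal(motif_score(p, argmin), 0)
  # degenerate uniform PSSM: every window scores 0.5 by convention
  uni <- matrix(1 / 20, 15, 20, dimnames = list(NULL, myosignal:::AA_ALPHABET))
  expect_equal(motif_score(uni, argmax), 0.5)
  expect_error(motif_score(p, strrep("-", 15)), "padding")
  # padded windows still score inside [0, 1]
  padded <- paste0("---", substr(argmax, 4, 15))
  s <- motif_score(p, padded)
  expect_gte(s, 0); expect_lte(s, 1)
})

test_that("profile and combined scores hit their boundary identities", {
  centroid <- c(1, -1, 0.5)
  expect_equal(profile_score(centroid, centroid), 1)
  expect_equal(profile_score(-centroid, centroid), 0)
  # orthogonal profile: r = 0 -> 0.5
  expect_equal(profile_score(c(-0.5, -0.5, 1), c(1, -1, 0)), 0.5)
  expect_true(is.na(profile_score(c(2, 2, 2), centroid)))

  expect_equal(combined_score(1, 1, 0.3), 1)
  expect_equal(combined_score(0, 0.8, 0.5), 0)
  expect_equal(combined_score(0.6, 0.9, 1), 0.6)
  # bounded by the components for interior weights
  set.seed(16)
  for (i in 1:50) {
    sm <- runif(1); sp <- runif(1); w <- runif(1, 0.05, 0.95)
    sc <- combined_score(sm, sp, w)
    expect_lte(sc, max(sm, sp) + 1e-12)
    expect_gte(sc, min(sm, sp) - 1e-12)
  }
})

test_that("score_all covers every site x eligible kinase pair", {
  sc <- run_timecourse_scenario(seed = 2, n_kinases = 4, n_background = 60)
  tab <- sc$scores
  n_sites <- length(unique(tab$site))
  n_kin <- length(unique(tab$kinase))
  expect_equal(nrow(tab), n_sites * n_kin)
  expect_true(all(tab$s_combined >= 0 & tab$s_combined <= 1, na.rm = TRUE))
  expect_true(all(tab$s_motif >= 0 & tab$s_motif <= 1))
  # annotated substrates are present and flagged
  ann <- sc$annotation
  flagged <- merge(ann, tab, by = c("kinase", "site"))
  expect_true(all(flagged$known))
  expect_error(score_all(data.frame(site = "s", window = "AAASAAA"),
                         matrix(0, 1, 2), ann[0, ]), "empty annotation")
  # determinism
  sc2 <- run_timecourse_scenario(seed = 2, n_kinases = 4, n_background = 60)
  expect_identical(tab, sc2$scores)
})

test_that("signalome edges count shared top-scoring substrate proteins", {
  tbl <- function(site, kinase, s)
    data.frame(site = site, kinase = kinase, s_combined = s,
               stringsAsFactors = FALSE)
  # disjoint substrate sets: no edge
  t1 <- rbind(tbl(c("P1_S1", "P2_S1"), "KA", 0.9),
              tbl(c("P1_S1", "P2_S1"), "KB", 0.2),
              tbl("P3_S1", "KA", 0.1), tbl("P3_S1", "KB", 0.8))
  s1 <- build_signalome(t1, assign_threshold = 0.5)
  expect_equal(nrow(s1$edges), 0)
  expect_setequal(s1$assignments$kinase[s1$assignments$site == "P1_S1"], "KA")

  # identical score columns: tied argmax -> lexicographic assignment, edge
  # weight equals the number of assigned proteins
  t2 <- rbind(tbl(paste0("P", 1:3, "_S1"), "KA", 0.8),
              tbl(paste0("P", 1:3, "_S1"), "KB", 0.8))
  s2 <- build_signalome(t2, assign_threshold = 0.5)
  expect_true(all(s2$assignments$kinase == "KA"))
  expect_equal(s2$edges$weight, 3)
  expect_setequal(s2$ties, paste0("P", 1:3, "_S1"))

  # planted overlap of 7 dual-specificity proteins
  dual <- paste0("D", 1:7, "_S1")
  own_a <- paste0("A", 1:4, "_S1"); own_b <- paste0("B", 1:5, "_S1")
  t3 <- rbind(tbl(dual, "KA", 0.9), tbl(dual, "KB", 0.9),
              tbl(own_a, "KA", 0.8), tbl(own_a, "KB", 0.1),
              tbl(own_b, "KA", 0.1), tbl(own_b, "KB", 0.8))
  s3 <- build_signalome(t3, assign_threshold = 0.5)
  expect_equal(s3$edges$weight[s3$edges$kinase1 == "KA" &
                                 s3$edges$kinase2 == "KB"], 7)
  # symmetry: reversing the input row order changes nothing
  s3r <- build_signalome(t3[rev(seq_len(nrow(t3))), ], assign_threshold = 0.5)
  expect_equal(s3$edges, s3r$edges)
})

test_that("specificity dissection applies the score and z rules", {
  tbl <- data.frame(site = c("s1", "s2", "s3", "s4"),
                    kinase = "MAPK1",
                    s_combined = c(0.8, 0.69, 0.9, 0.75),
                    stringsAsFactors = FALSE)
  tbl2 <- tbl; tbl2$kinase <- "MAPK8"; tbl2$s_combined <- c(0.1, 0.1, 0.2, 0.1)
  zmat <- matrix(c(-2, 0,    # s1: more inhibited by PD
                   -3, -1,   # s2: below score threshold
                   1, -1,    # s3: more inhibited by SP
                   0.5, 0.5),# s4: tie -> unassigned
                 4, 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2", "s3", "s4"), c("PD", "SP")))
  res <- dissect_specificity(rbind(tbl, tbl2), zmat,
                             list("MAPK1/3" = "MAPK1", "MAPK8/9" = "MAPK8"),
                             score_threshold = 0.7)
  expect_false("s2" %in% res$site)
  expect_equal(res$group[res$site == "s1"], "MAPK1/3")
  expect_equal(res$group[res$site == "s3"], "MAPK8/9")
  expect_true(is.na(res$group[res$site == "s4"]))
  expect_identical(attr(res, "unassigned"), "s4")

  # candidate without inhibition values is excluded and reported
  z2 <- zmat[c("s3", "s4"), ]
  res2 <- dissect_specificity(rbind(tbl, tbl2), z2,
                              list("MAPK1/3" = "MAPK1", "MAPK8/9" = "MAPK8"))
  expect_false("s1" %in% res2$site)
  expect_identical(attr(res2, "excluded"), "s1")
})

# (the window-shuffle chance-level control lives in test-acceptance.R,
# averaged over shuffles for statistical soundness)
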