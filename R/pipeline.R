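#' @name pipelines
#' @title End-to-end synthetic-benchmark scenarios
#'
#' @description
#' Wrappers that run the full pipeline on seeded synthetic data and score
#' recovery of the planted ground truth. They serve as executable
#' benchmarks: each returns the metrics a user would inspect to trust the
#' machinery (activity-recovery correlations, held-out substrate AUROC,
#' inhibitor-dissection accuracy, cluster and event-order recovery, DE
#' sensitivity and observed FDR).
NULL

timecourse_conditions <- function() c("0h", "30m", "24h", "d5")

#' Time-course phosphoproteome scenario
#'
#' Simulates the 4-time-point x 4-replicate x 2-batch phosphoproteome
#' design with planted kinases, runs filtering, two-stage imputation, ratio
#' conversion, batch correction and control-feature normalisation, then
#' infers kinase activities and predicts substrates, scoring both against
#' the planted truth.
#'
#' @param seed integer seed driving all randomness.
#' @param n_kinases,n_substrates,n_background simulation sizes.
#' @param noise_sd,batch_sd,mnar_quantile,mcar_rate noise and missingness.
#' @param motif_informativeness planted motif strength.
#' @param known_fraction,min_known annotation coverage.
#' @param ruv_k unwanted-variation factors removed (0 disables).
#' @return list with `metrics` (named numerics: per-contrast activity
#'   Spearman rho and their min, pooled held-out AUROC for combined, motif
#'   and profile scores, per-condition ratio-recovery Pearson r, feature
#'   counts) and the intermediate objects (`zmat`, `activity`, `scores`,
#'   `annotation`, `sim`).
#' @export
run_timecourse_scenario <- function(seed = 1, n_kinases = 10,
                                    n_substrates = 20, n_background = 200,
                                    noise_sd = 0.5, batch_sd = 0.5,
                                    mnar_quantile = 0.1, mcar_rate = 0.05,
                                    motif_informativeness = 0.7,
                                    known_fraction = 0.5, min_known = 5,
                                    ruv_k = 1) {
  conditions <- timecourse_conditions()
  design <- make_design(conditions, n_replicates = 4, n_batches = 2)
  models <- make_kinase_models(n_kinases, window_len = 15,
                               motif_informativeness = motif_informativeness,
                               conditions = conditions,
                               n_true_substrates = n_substrates, seed = seed)
  sim <- simulate_phospho(models, design = design,
                          n_background = n_background, noise_sd = noise_sd,
                          batch_sd = batch_sd,
                          mnar_quantile = mnar_quantile,
                          mcar_rate = mcar_rate, seed = seed)
  filtered <- filter_features(sim$quant, filter_rule(4, 3, 1))
  imp <- impute_condition_specific(filtered, seed = seed)
  imp <- impute_random_tail(imp, seed = seed)
  ratios <- to_ratios(imp, "0h")
  norm <- correct_batch(ratios, "center")
  if (ruv_k > 0) {
    controls <- select_stable_features(norm,
                                       n = max(20, round(0.1 * nrow(norm$values))))
    norm <- ruv_normalize(norm, controls, k = ruv_k)
  }
  zmat <- standardize(norm)
  annotation <- subset_known_substrates(sim$truth,
                                        known_fraction = known_fraction,
                                        min_known = min_known, seed = seed)
  activity <- kinase_activity_timecourse(zmat, annotation,
                                         min_substrates = min_known)
  # activity recovery: Spearman between planted activity and inferred Z,
  # per contrast
  rho <- vapply(setdiff(conditions, "0h"), function(cc) {
    sub <- activity[activity$contrast == paste0(cc, "-vs-0h"), ]
    stats::cor(sim$truth$activities[sub$kinase, cc], sub$Z,
               method = "spearman")
  }, numeric(1))
  scores <- score_all(sim$windows[, c("site", "window")], zmat, annotation,
                      min_known = min_known)
  # held-out recovery, pooled over kinases: held-out true substrates vs
  # background sites (each kinase's known substrates excluded)
  held <- attr(annotation, "held_out")
  background <- names(sim$truth$site2kinase)[is.na(sim$truth$site2kinase)]
  pool <- do.call(rbind, lapply(unique(scores$kinase), function(k) {
    pos <- intersect(held$site[held$kinase == k], scores$site)
    sub <- scores[scores$kinase == k &
                    scores$site %in% c(pos, background), ]
    sub$label <- sub$site %in% pos
    sub
  }))
  auc <- c(combined = auroc(pool$s_combined, pool$label),
           motif = auroc(pool$s_motif, pool$label),
           profile = auroc(pool$s_profile, pool$label))
  # end-to-end ratio recovery vs planted effects
  r_cond <- vapply(setdiff(conditions, "0h"), function(cc) {
    est <- rowMeans(norm$values[, norm$design$condition == cc, drop = FALSE])
    stats::cor(est, sim$truth$true_effect[rownames(norm$values), cc])
  }, numeric(1))
  metrics <- c(stats::setNames(rho, paste0("activity_rho_", names(rho))),
               activity_rho_min = min(rho),
               auroc_combined = auc[["combined"]],
               auroc_motif = auc[["motif"]],
               auroc_profile = auc[["profile"]],
               stats::setNames(r_cond, paste0("ratio_recovery_r_",
                                              names(r_cond))),
               ratio_recovery_r_min = min(r_cond),
               n_sites_simulated = nrow(sim$quant$values),
               n_sites_retained = nrow(norm$values))
  list(metrics = metrics, zmat = zmat, activity = activity, scores = scores,
       annotation = annotation, sim = sim, norm = norm)
}

#' Inhibitor-perturbation scenario (PD vs SP)
#'
#' Simulates a 3-condition (control / PD / SP) x 4-replicate design with one
#' kinase inhibited by PD only, one by SP only and the rest inactive, then
#' runs direction-based kinase analysis and inhibitor-specificity
#' dissection against the planted truth.
#'
#' @param seed integer seed.
#' @param n_kinases total kinases (>= 2; the first two are the PD- and
#'   SP-inhibited ones).
#' @param n_substrates substrates per kinase.
#' @param n_background background sites.
#' @param inhibition_effect planted log2 effect of inhibition (applied
#'   negatively).
#' @param noise_sd residual sd.
#' @param score_threshold dissection candidate threshold.
#' @return list with `metrics` (top kinase identity and rank in the
#'   "inhibited by PD only" direction, |Z| contrast between directions,
#'   dissection partition accuracy and counts) plus intermediates.
#' @export
run_inhibition_scenario <- function(seed = 1, n_kinases = 8,
                                    n_substrates = 20, n_background = 200,
                                    inhibition_effect = 2, noise_sd = 0.5,
                                    score_threshold = 0.7) {
  stopifnot(n_kinases >= 2)
  conditions <- c("ctrl", "PD", "SP")
  design <- make_design(conditions, n_replicates = 4, n_batches = 1)
  models <- make_kinase_models(n_kinases, motif_informativeness = 0.7,
                               conditions = conditions, activity_sd = 0,
                               n_true_substrates = n_substrates, seed = seed)
  models[[1]]$activity <- c(ctrl = 0, PD = -inhibition_effect, SP = 0)
  models[[2]]$activity <- c(ctrl = 0, PD = 0, SP = -inhibition_effect)
  pd_kinase <- models[[1]]$kinase_id
  sp_kinase <- models[[2]]$kinase_id
  sim <- simulate_phospho(models, design = design,
                          n_background = n_background, noise_sd = noise_sd,
                          batch_sd = 0, mnar_quantile = 0.05,
                          mcar_rate = 0.05, seed = seed)
  filtered <- filter_features(sim$quant, filter_rule(3, 3, 1))
  imp <- impute_random_tail(impute_condition_specific(filtered, seed = seed),
                            seed = seed)
  ratios <- to_ratios(imp, "ctrl")
  zmat <- standardize(ratios, contrasts = c(PD = "PD", SP = "SP"))
  annotation <- subset_known_substrates(sim$truth, known_fraction = 0.5,
                                        min_known = 5, seed = seed)
  kda <- kinase_direction_analysis(zmat, annotation)
  pd_dir <- kda[kda$direction == "inhibited by PD only", ]
  pd_dir <- pd_dir[order(-pd_dir$Z), ]
  sp_dir <- kda[kda$direction == "inhibited by SP only", ]
  scores <- score_all(sim$windows[, c("site", "window")], zmat, annotation,
                      min_known = 5)
  groups <- stats::setNames(list(pd_kinase, sp_kinase),
                            c(pd_kinase, sp_kinase))
  diss <- dissect_specificity(scores, zmat, groups,
                              score_threshold = score_threshold)
  s2k <- sim$truth$site2kinase
  truth_grp <- s2k[diss$site]
  eval_rows <- !is.na(truth_grp) & truth_grp %in% c(pd_kinase, sp_kinase) &
    !is.na(diss$group)
  accuracy <- if (any(eval_rows))
    mean(diss$group[eval_rows] == truth_grp[eval_rows]) else NA_real_
  metrics <- c(pd_top_rank = which(pd_dir$kinase == pd_kinase)[1],
               pd_Z_in_pd_direction = pd_dir$Z[pd_dir$kinase == pd_kinase],
               pd_absZ_in_sp_direction =
                 abs(sp_dir$Z[sp_dir$kinase == pd_kinase]),
               dissection_accuracy = accuracy,
               n_candidates = nrow(diss),
               n_true_candidates = sum(eval_rows))
  list(metrics = metrics, kda = kda, dissection = diss, zmat = zmat,
       sim = sim, pd_kinase = pd_kinase, sp_kinase = sp_kinase)
}

#' Proteome time-course clustering scenario
#'
#' Simulates the 8-time-point proteome design with four planted temporal
#' clusters (staggered step profiles, one pathway term each), calls
#' dynamically regulated proteins, z-transforms their fold-change profiles,
#' sweeps k with enrichment guidance and orders the cluster events,
#' comparing everything against the planted truth.
#'
#' @param seed integer seed.
#' @param n_proteins simulated proteins.
#' @param k_range candidate cluster numbers.
#' @param n_starts k-means restarts.
#' @return list with `metrics` (`k_star`, `ari`, `event_order_exact`,
#'   `n_dynamic`, dynamic-call sensitivity/specificity) and intermediates.
#' @export
run_proteome_clustering_scenario <- function(seed = 1, n_proteins = 200,
                                             k_range = 2:8, n_starts = 10) {
  conditions <- c("0h", "30m", "1h", "6h", "12h", "24h", "d3", "d5")
  times <- c(0, 0.5, 1, 6, 12, 24, 72, 120)
  design <- make_design(conditions, n_replicates = 4, n_batches = 1)
  sim <- simulate_proteome(design, n_proteins = n_proteins, n_clusters = 4,
                           frac_background = 0.5, amplitude = 2,
                           noise_sd = 0.5, seed = seed)
  filtered <- filter_features(sim$quant,
                              filter_rule(4, 2, 2, adjacency_required = TRUE))
  imp <- impute_random_tail(impute_condition_specific(filtered, seed = seed),
                            seed = seed)
  ratios <- to_ratios(imp, "0h")
  dyn <- dynamic_call(ratios)
  truth_dyn <- sim$truth$dynamic[dyn$feature]
  sens <- mean(dyn$dynamic[truth_dyn])
  specif <- mean(!dyn$dynamic[!truth_dyn])
  fc <- vapply(conditions, function(cc)
    rowMeans(ratios$values[, ratios$design$condition == cc, drop = FALSE]),
    numeric(nrow(ratios$values)))
  z <- ztransform_profiles(fc[dyn$feature[dyn$dynamic], , drop = FALSE])
  terms <- data.frame(term = sim$truth$pathways$term,
                      feature = sim$truth$pathways$protein,
                      stringsAsFactors = FALSE)
  cs <- cluster_sweep(z, k_range = k_range, terms = terms,
                      n_starts = n_starts, seed = seed)
  planted <- sim$truth$cluster
  names(planted) <- rownames(sim$truth$true_effect)
  common <- names(cs$membership)[!is.na(planted[names(cs$membership)])]
  ari <- mclust::adjustedRandIndex(cs$membership[common], planted[common])
  centroids <- cluster_centroids(z, cs$membership)
  ev <- event_times(centroids, times)
  # map each recovered cluster to its dominant planted cluster and compare
  # the recovered event order with the planted switch order (planted
  # cluster c switches later for larger c)
  dominant <- vapply(rownames(centroids), function(cl) {
    members <- names(cs$membership)[cs$membership == cl]
    pl <- planted[members]
    pl <- pl[!is.na(pl)]
    if (length(pl) == 0) return(NA_integer_)
    as.integer(names(sort(table(pl), decreasing = TRUE))[1])
  }, integer(1))
  recovered_order <- dominant[ev$cluster]
  event_order_exact <- length(recovered_order) == 4 &&
    !anyNA(recovered_order) &&
    identical(as.integer(recovered_order), 1:4)
  metrics <- c(k_star = cs$k_star, ari = ari,
               event_order_exact = as.numeric(event_order_exact),
               n_dynamic = sum(dyn$dynamic),
               dynamic_sensitivity = sens, dynamic_specificity = specif)
  list(metrics = metrics, cluster_result = cs, events = ev, dynamics = dyn,
       sim = sim, times = times, dominant = dominant)
}

#' Overexpression differential-expression scenario
#'
#' Simulates a three-condition overexpression design (reference, wild type,
#' mutant) with planted DE proteins in the wild type, runs the two-stage
#' reference-normalized moderated t-test and scores sensitivity and the
#' observed false discovery rate.
#'
#' @param seed integer seed.
#' @param n_proteins,n_de totals and planted DE count.
#' @param effect planted log2 effect (alternating sign).
#' @param n_reps replicates per condition.
#' @param noise_sd residual sd.
#' @return list with `metrics` (`sensitivity`, `observed_fdr`, `n_called`)
#'   and the DE table.
#' @export
run_overexpression_scenario <- function(seed = 1, n_proteins = 500,
                                        n_de = 50, effect = 2, n_reps = 4,
                                        noise_sd = 0.5) {
  set.seed(seed + 7L)
  conditions <- c("GFP", "WT", "mut")
  design <- make_design(conditions, n_replicates = n_reps, n_batches = 1)
  proteins <- sprintf("PROT%04d", seq_len(n_proteins))
  truth_de <- c(rep(TRUE, n_de), rep(FALSE, n_proteins - n_de))
  eff <- ifelse(truth_de, effect * rep_len(c(1, -1), n_proteins), 0)
  baseline <- stats::rnorm(n_proteins, 27, 2)
  vals <- matrix(0, n_proteins, nrow(design),
                 dimnames = list(proteins, design$sample))
  for (s in seq_len(nrow(design))) {
    vals[, s] <- baseline +
      (design$condition[s] == "WT") * eff +
      stats::rnorm(n_proteins, 0, noise_sd)
  }
  m <- quant_matrix(vals, design, scale = "intensity")
  de <- contrast_vs_reference_de(m, "WT", "mut", "GFP")
  called <- de$de
  sens <- mean(called[truth_de])
  fdr <- if (sum(called) > 0) sum(called & !truth_de) / sum(called) else 0
  list(metrics = c(sensitivity = sens, observed_fdr = fdr,
                   n_called = sum(called)),
       de = de, truth_de = stats::setNames(truth_de, proteins))
}
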