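#' @name synth
#' @title Synthetic phosphoproteome generator with planted ground truth
#'
#' @description
#' Generators that emulate the structure of time-resolved and
#' inhibitor-perturbed phosphoproteome/proteome experiments: kinases with
#' sequence motifs (PSSMs over the +/-7 flanking window) and per-condition
#' activities, substrate sites whose log2 intensities follow their kinase's
#' activity, background sites, additive batch effects, intensity-dependent
#' (left-censored) and random missingness, and matching ground-truth tables
#' so recovery can be scored at every downstream stage.
NULL

# 20 standard residues; "-" pads windows truncated at protein termini and
# contributes nothing to motif counts or scores.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PAD_SYMBOL <- "-"

#' Generate kinase models with motifs and planted activities
#'
#' Each kinase gets a position-specific scoring matrix (PSSM) over a 15-mer
#' flanking window whose centre is fixed to the phosphoacceptor (S/T), and a
#' per-condition log2 activity vector (0 at the reference condition). At each
#' non-centre position the residue distribution is a mixture
#' `(1 - m) * uniform + m * point-mass` on a randomly chosen preferred
#' residue, so the mean per-position Kullback-Leibler divergence from uniform
#' grows monotonically with the informativeness `m`.
#'
#' @param n_kinases number of kinases (>= 1).
#' @param window_len odd window length (default 15, i.e. +/-7).
#' @param motif_informativeness mixture weight m in \[0, 1\]; 0 gives uniform
#'   columns, 1 gives deterministic motifs.
#' @param conditions condition labels; the first is the reference.
#' @param activity_sd sd (log2 units) of planted activities at non-reference
#'   conditions.
#' @param n_true_substrates substrates planted per kinase.
#' @param seed integer seed.
#' @return list of kinase models, each a list with `kinase_id`, `pssm`
#'   (window_len x 20 matrix of per-position residue probabilities, rows
#'   summing to 1), `activity` (named per-condition vector) and
#'   `n_true_substrates`.
#' @export
make_kinase_models <- function(n_kinases, window_len = 15,
                               motif_informativeness = 0.7,
                               conditions = c("0h", "30m", "24h", "d5"),
                               activity_sd = 2, n_true_substrates = 20,
                               seed = 1) {
  stopifnot(n_kinases >= 1, n_true_substrates >= 1)
  if (window_len %% 2 != 1) stop("window_len must be odd")
  if (motif_informativeness < 0 || motif_informativeness > 1)
    stop("motif_informativeness must be in [0, 1]")
  set.seed(seed)
  centre <- (window_len + 1) / 2
  lapply(seq_len(n_kinases), function(i) {
    pssm <- matrix(1 / 20, nrow = window_len, ncol = 20,
                   dimnames = list(NULL, AA_ALPHABET))
    for (p in seq_len(window_len)) {
      if (p == centre) next
      preferred <- sample(AA_ALPHABET, 1)
      col <- rep((1 - motif_informativeness) / 20, 20)
      names(col) <- AA_ALPHABET
      col[preferred] <- col[preferred] + motif_informativeness
      pssm[p, ] <- col
    }
    # phosphoacceptor: S or T, equally likely
    pssm[centre, ] <- 0
    pssm[centre, c("S", "T")] <- 0.5
    activity <- c(0, stats::rnorm(length(conditions) - 1, 0, activity_sd))
    names(activity) <- conditions
    list(kinase_id = sprintf("KIN%02d", i), pssm = pssm,
         activity = activity, n_true_substrates = n_true_substrates)
  })
}

#' Sample flanking windows from a PSSM
#'
#' @param pssm positions x residues probability matrix (rows sum to 1).
#' @param n number of windows.
#' @return character vector of windows.
#' @export
sample_windows <- function(pssm, n) {
  L <- nrow(pssm)
  chars <- vapply(seq_len(L), function(p)
    sample(colnames(pssm), n, replace = TRUE, prob = pssm[p, ]),
    character(n))
  if (n == 1) chars <- matrix(chars, nrow = 1)
  apply(chars, 1, paste, collapse = "")
}

uniform_window <- function(window_len) {
  centre <- (window_len + 1) / 2
  ch <- sample(AA_ALPHABET, window_len, replace = TRUE)
  ch[centre] <- sample(c("S", "T"), 1)
  paste(ch, collapse = "")
}

#' Simulate a phosphoproteome quantification experiment
#'
#' Substrate site log2 intensity at condition c is
#' `baseline + activity_kinase[c] + batch_shift + N(0, noise_sd)`; flanking
#' windows of substrates are drawn from the assigned kinase's PSSM and
#' background windows from the uniform alphabet. Missingness is applied in
#' two layers: cells below the per-sample `mnar_quantile` of the complete
#' (latent) matrix are censored, then a fraction `mcar_rate` of the remaining
#' cells is removed at random.
#'
#' @param models output of [make_kinase_models()].
#' @param n_sites_per_kinase substrate sites per kinase (defaults to each
#'   model's `n_true_substrates`).
#' @param n_background unregulated background sites.
#' @param design sample design from [make_design()]; its conditions must
#'   match the models' activity names.
#' @param noise_sd,batch_sd residual and batch-effect sd (log2 units).
#' @param mnar_quantile per-sample left-censoring quantile in \[0, 1\].
#' @param mcar_rate random missingness rate in \[0, 1\].
#' @param baseline_mean,baseline_sd distribution of per-site baseline
#'   abundance (log2).
#' @param seed integer seed.
#' @return list with `quant` (a `QuantMatrix`, intensity scale), `windows`
#'   (data.frame: site, protein, position, window) and `truth` (list:
#'   `site2kinase` named vector with `NA` for background, `activities`
#'   kinase x condition matrix, `true_effect` site x condition matrix,
#'   `latent` complete pre-missingness matrix, `batch_shift`, `dynamic`
#'   logical per site).
#' @export
simulate_phospho <- function(models, n_sites_per_kinase = NULL,
                             n_background = 100, design,
                             noise_sd = 0.5, batch_sd = 0.5,
                             mnar_quantile = 0.1, mcar_rate = 0.05,
                             baseline_mean = 25, baseline_sd = 2,
                             seed = 1) {
  if (length(models) == 0 && (is.null(n_sites_per_kinase) ||
                              n_sites_per_kinase > 0))
    stop("empty model list with substrate sites requested")
  stopifnot(mnar_quantile >= 0, mnar_quantile <= 1,
            mcar_rate >= 0, mcar_rate <= 1)
  conditions <- levels(design$condition)
  for (m in models)
    if (!identical(names(m$activity), conditions))
      stop("model conditions do not match design conditions")
  set.seed(seed)

  n_per <- vapply(models, function(m) {
    as.integer(if (is.null(n_sites_per_kinase)) m$n_true_substrates
               else n_sites_per_kinase)
  }, integer(1))
  n_sub <- sum(n_per)
  n_sites <- n_sub + n_background
  site_kinase <- c(rep(vapply(models, `[[`, character(1), "kinase_id"),
                       times = n_per),
                   rep(NA_character_, n_background))
  proteins <- sprintf("PROT%04d", seq_len(n_sites))
  positions <- sample(20:400, n_sites, replace = TRUE)
  sites <- sprintf("%s_S%d", proteins, positions)

  window_len <- if (length(models) > 0) nrow(models[[1]]$pssm) else 15
  windows <- character(n_sites)
  idx <- 1
  for (j in seq_along(models)) {
    if (n_per[j] > 0) {
      windows[idx:(idx + n_per[j] - 1)] <- sample_windows(models[[j]]$pssm,
                                                          n_per[j])
      idx <- idx + n_per[j]
    }
  }
  if (n_background > 0)
    windows[(n_sub + 1):n_sites] <-
      vapply(seq_len(n_background), function(i) uniform_window(window_len),
             character(1))

  activities <- do.call(rbind, lapply(models, `[[`, "activity"))
  if (length(models) > 0)
    rownames(activities) <- vapply(models, `[[`, character(1), "kinase_id")
  true_effect <- matrix(0, n_sites, length(conditions),
                        dimnames = list(sites, conditions))
  is_sub <- !is.na(site_kinase)
  if (any(is_sub))
    true_effect[is_sub, ] <- activities[site_kinase[is_sub], , drop = FALSE]

  n_samp <- nrow(design)
  baseline <- stats::rnorm(n_sites, baseline_mean, baseline_sd)
  batches <- unique(design$batch)
  batch_shift <- matrix(stats::rnorm(n_sites * length(batches), 0, batch_sd),
                        n_sites, length(batches),
                        dimnames = list(sites, batches))
  latent <- matrix(0, n_sites, n_samp, dimnames = list(sites, design$sample))
  for (s in seq_len(n_samp)) {
    cond <- as.character(design$condition[s])
    latent[, s] <- baseline + true_effect[, cond] +
      batch_shift[, design$batch[s]] +
      stats::rnorm(n_sites, 0, noise_sd)
  }

  observed <- latent
  if (mnar_quantile > 0) {
    for (s in seq_len(n_samp)) {
      thr <- stats::quantile(latent[, s], mnar_quantile)
      observed[latent[, s] < thr, s] <- NA
    }
  }
  if (mcar_rate > 0) {
    ok <- which(!is.na(observed))
    drop <- ok[stats::runif(length(ok)) < mcar_rate]
    observed[drop] <- NA
  }

  qm <- quant_matrix(observed, design, scale = "intensity")
  win_df <- data.frame(site = sites, protein = proteins,
                       position = positions, window = windows,
                       stringsAsFactors = FALSE)
  names(site_kinase) <- sites
  truth <- list(site2kinase = site_kinase, activities = activities,
                true_effect = true_effect, latent = latent,
                batch_shift = batch_shift,
                dynamic = apply(abs(true_effect) > 0, 1, any))
  list(quant = qm, windows = win_df, truth = truth)
}

#' Simulate a proteome quantification experiment
#'
#' Two planting modes. With `phospho_truth` supplied, the first proteins are
#' matched to phosphosite host proteins and their per-condition log2 effect
#' is `coupling * phospho_effect + sqrt(1 - coupling^2) * independent`, so
#' `coupling = 1` reproduces the host site's trend exactly and `coupling = 0`
#' makes trends independent. Otherwise proteins are planted into
#' `n_clusters` temporal clusters with staggered step-like profiles (half
#' up, half down, switching at successive time points), plus unregulated
#' background; one pathway term per cluster covers its members.
#'
#' @param design sample design from [make_design()].
#' @param n_proteins number of proteins.
#' @param coupling_to_phospho coupling in \[0, 1\] (used with
#'   `phospho_truth`).
#' @param phospho_truth optional `truth` element from [simulate_phospho()].
#' @param n_clusters planted temporal clusters (cluster mode).
#' @param frac_background fraction of unregulated proteins (cluster mode).
#' @param amplitude step size (log2) of cluster profiles.
#' @param noise_sd,batch_sd,mnar_quantile,mcar_rate as in
#'   [simulate_phospho()].
#' @param seed integer seed.
#' @return list with `quant`, and `truth` (list: `true_effect`, `cluster`
#'   integer per protein with `NA` for background, `pathways` data.frame
#'   (term, protein), `latent`, `dynamic`).
#' @export
simulate_proteome <- function(design, n_proteins = 200,
                              coupling_to_phospho = 0, phospho_truth = NULL,
                              n_clusters = 4, frac_background = 0.5,
                              amplitude = 2, noise_sd = 0.5, batch_sd = 0,
                              mnar_quantile = 0.05, mcar_rate = 0.02,
                              seed = 1) {
  stopifnot(coupling_to_phospho >= 0, coupling_to_phospho <= 1)
  set.seed(seed + 1L)
  conditions <- levels(design$condition)
  n_cond <- length(conditions)
  proteins <- sprintf("PROT%04d", seq_len(n_proteins))
  true_effect <- matrix(0, n_proteins, n_cond,
                        dimnames = list(proteins, conditions))
  cluster <- rep(NA_integer_, n_proteins)
  pathways <- NULL

  if (!is.null(phospho_truth)) {
    host_eff <- phospho_truth$true_effect
    hosts <- sub("_S[0-9]+$", "", rownames(host_eff))
    n_match <- min(n_proteins, nrow(host_eff))
    proteins[seq_len(n_match)] <- hosts[seq_len(n_match)]
    rownames(true_effect) <- proteins
    shared <- intersect(conditions, colnames(host_eff))
    cpl <- coupling_to_phospho
    for (i in seq_len(n_match)) {
      indep <- stats::rnorm(length(shared), 0, 1)
      true_effect[i, shared] <- cpl * host_eff[i, shared] +
        sqrt(1 - cpl^2) * indep
    }
  } else {
    n_bg <- round(n_proteins * frac_background)
    n_reg <- n_proteins - n_bg
    if (n_reg > 0 && n_clusters > 0) {
      cl <- rep(seq_len(n_clusters), length.out = n_reg)
      cl <- sort(cl)
      cluster[seq_len(n_reg)] <- cl
      # step profiles: cluster c switches after time index 1 + (c-1) mod
      # (n_cond - 1); odd clusters step up, even clusters step down
      for (c in seq_len(n_clusters)) {
        switch_at <- 1 + ((c - 1) %% (n_cond - 1))
        prof <- rep(0, n_cond)
        prof[(switch_at + 1):n_cond] <- amplitude * if (c %% 2 == 1) 1 else -1
        members <- which(cluster == c)
        true_effect[members, ] <- matrix(prof, length(members), n_cond,
                                         byrow = TRUE)
      }
      pathways <- data.frame(term = sprintf("TERM%02d", cluster[seq_len(n_reg)]),
                             protein = proteins[seq_len(n_reg)],
                             stringsAsFactors = FALSE)
    }
  }

  n_samp <- nrow(design)
  baseline <- stats::rnorm(n_proteins, 27, 2)
  batches <- unique(design$batch)
  batch_shift <- matrix(stats::rnorm(n_proteins * length(batches), 0, batch_sd),
                        n_proteins, length(batches),
                        dimnames = list(proteins, batches))
  latent <- matrix(0, n_proteins, n_samp,
                   dimnames = list(proteins, design$sample))
  for (s in seq_len(n_samp)) {
    cond <- as.character(design$condition[s])
    latent[, s] <- baseline + true_effect[, cond] +
      batch_shift[, design$batch[s]] +
      stats::rnorm(n_proteins, 0, noise_sd)
  }
  observed <- latent
  if (mnar_quantile > 0)
    for (s in seq_len(n_samp)) {
      thr <- stats::quantile(latent[, s], mnar_quantile)
      observed[latent[, s] < thr, s] <- NA
    }
  if (mcar_rate > 0) {
    ok <- which(!is.na(observed))
    observed[ok[stats::runif(length(ok)) < mcar_rate]] <- NA
  }
  qm <- quant_matrix(observed, design, scale = "intensity")
  list(quant = qm,
       truth = list(true_effect = true_effect, cluster = cluster,
                    pathways = pathways, latent = latent,
                    dynamic = apply(abs(true_effect) > 1, 1, sum) >= 2))
}

#' Subset planted substrates into a known-substrate annotation
#'
#' Emulates a curated kinase-substrate database that covers only part of the
#' truth: per kinase, `floor(known_fraction * n_true)` substrates (at least
#' `min_known`) are flagged known; the remainder are withheld as held-out
#' positives for recovery benchmarks.
#'
#' @param truth the `truth` element of [simulate_phospho()].
#' @param known_fraction fraction in (0, 1\].
#' @param min_known minimum known substrates per kinase.
#' @param seed integer seed.
#' @return data.frame (kinase, site) of known substrates, with the held-out
#'   complement in `attr(, "held_out")`.
#' @export
subset_known_substrates <- function(truth, known_fraction = 0.5,
                                    min_known = 1, seed = 1) {
  stopifnot(known_fraction > 0, known_fraction <= 1)
  set.seed(seed + 2L)
  s2k <- truth$site2kinase
  kinases <- rownames(truth$activities)
  known <- list(); held <- list()
  for (k in kinases) {
    subs <- names(s2k)[!is.na(s2k) & s2k == k]
    if (length(subs) < min_known)
      stop(sprintf("kinase %s has %d true substrates, fewer than min_known = %d",
                   k, length(subs), min_known))
    n_known <- max(min_known, floor(known_fraction * length(subs)))
    pick <- sort(sample(subs, n_known))
    rest <- sort(setdiff(subs, pick))
    known[[k]] <- data.frame(kinase = rep(k, length(pick)), site = pick,
                             stringsAsFactors = FALSE)
    held[[k]] <- data.frame(kinase = rep(k, length(rest)), site = rest,
                            stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, known)
  rownames(ann) <- NULL
  ho <- do.call(rbind, held)
  rownames(ho) <- NULL
  attr(ann, "held_out") <- ho
  ann
}

#' Simulate a cells x genes count matrix with a marker-gated population
#'
#' Target cells (the population a `Myf5+/Myod1+ and Myog-` gate should
#' capture) express Myf5 and/or Myod1 at Poisson(`marker_rate`) + 1 counts
#' and have zero Myog; non-target cells express Myog. Non-marker genes are
#' Poisson background except a planted set of high-variance genes.
#'
#' @param n_cells number of cells.
#' @param n_genes total genes including the three markers.
#' @param frac_target fraction of gated-in (target) cells.
#' @param n_hvg number of planted high-variance genes.
#' @param marker_rate Poisson rate of positive markers.
#' @param seed integer seed.
#' @return list with `counts` (cells x genes integer matrix), `truth`
#'   (logical per cell, TRUE = target) and `hvg` (planted high-variance
#'   gene names).
#' @export
simulate_expression <- function(n_cells = 200, n_genes = 300,
                                frac_target = 0.5, n_hvg = 20,
                                marker_rate = 5, seed = 1) {
  stopifnot(n_genes >= 10)
  set.seed(seed + 3L)
  markers <- c("Myf5", "Myod1", "Myog")
  others <- sprintf("Gene%04d", seq_len(n_genes - 3))
  genes <- c(markers, others)
  target <- c(rep(TRUE, round(n_cells * frac_target)),
              rep(FALSE, n_cells - round(n_cells * frac_target)))
  counts <- matrix(stats::rpois(n_cells * n_genes, 1), n_cells, n_genes,
                   dimnames = list(sprintf("cell%04d", seq_len(n_cells)),
                                   genes))
  hvg <- sample(others, n_hvg)
  for (g in hvg) {
    mu <- stats::rexp(n_cells, 1 / 10)  # overdispersed: Poisson-Gamma
    counts[, g] <- stats::rpois(n_cells, mu)
  }
  # gate-defining structure: exactly one of Myf5/Myod1 guaranteed positive
  # in targets, Myog strictly positive in non-targets
  use_myf5 <- stats::runif(n_cells) < 0.5
  counts[, "Myf5"] <- ifelse(target & use_myf5,
                             stats::rpois(n_cells, marker_rate) + 1, 0)
  counts[, "Myod1"] <- ifelse(target & !use_myf5,
                              stats::rpois(n_cells, marker_rate) + 1, 0)
  counts[, "Myog"] <- ifelse(target, 0, stats::rpois(n_cells, marker_rate) + 1)
  list(counts = counts, truth = target, hvg = hvg)
}
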