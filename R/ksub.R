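#' Build a position-specific scoring matrix from substrate windows
#'
#' Residue counts per window position with additive pseudocount `alpha`;
#' padding symbols (`-`, windows truncated at protein termini) are excluded
#' position-wise, so probability at (position, residue) is
#' `(count + alpha) / (n_non_pad + 20 * alpha)`.
#'
#' @param windows character vector of equal-length flanking windows of one
#'   kinase's known substrates.
#' @param alpha pseudocount (> 0).
#' @param min_known minimum number of windows required.
#' @return list of class `PSSM`: `prob` (positions x 20, rows sum to 1),
#'   `alpha`, `n_sequences`.
#' @export
build_pssm <- function(windows, alpha = 0.01, min_known = 5) {
  stopifnot(alpha > 0)
  if (length(windows) < min_known)
    stop(sprintf("need at least %d windows, got %d", min_known,
                 length(windows)))
  L <- unique(nchar(windows))
  if (length(L) != 1) stop("windows differ in length")
  chars <- do.call(rbind, strsplit(windows, ""))
  prob <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  for (p in seq_len(L)) {
    col <- chars[, p]
    col <- col[col != PAD_SYMBOL]
    cnt <- table(factor(col, levels = AA_ALPHABET))
    prob[p, ] <- (as.numeric(cnt) + alpha) / (length(col) + 20 * alpha)
  }
  structure(list(prob = prob, alpha = alpha, n_sequences = length(windows)),
            class = "PSSM")
}

#' Motif match score of a window against a PSSM
#'
#' Raw score is the mean log-probability over non-padding positions; it is
#' min-max normalized by the best and worst achievable raw scores under the
#' PSSM (per-position max/min log-probability over the same positions),
#' giving a match score in \[0, 1\]: the PSSM's own argmax window scores 1,
#' the argmin window 0. A fully degenerate (uniform) PSSM, where best and
#' worst coincide, scores 0.5 by convention.
#'
#' @param pssm a [build_pssm()] result, or a bare positions x residues
#'   probability matrix.
#' @param window character window of matching length.
#' @return motif score in \[0, 1\].
#' @export
motif_score <- function(pssm, window) {
  prob <- if (inherits(pssm, "PSSM")) pssm$prob else pssm
  ch <- strsplit(window, "")[[1]]
  if (length(ch) != nrow(prob)) stop("window length does not match PSSM")
  use <- which(ch != PAD_SYMBOL)
  if (length(use) == 0) stop("all-padding window")
  lp <- log(pmax(prob, 1e-10))
  raw <- mean(lp[cbind(use, match(ch[use], colnames(prob)))])
  raw_max <- mean(apply(lp[use, , drop = FALSE], 1, max))
  raw_min <- mean(apply(lp[use, , drop = FALSE], 1, min))
  if (raw_max - raw_min < 1e-12) return(0.5)
  (raw - raw_min) / (raw_max - raw_min)
}

#' Temporal profile similarity score
#'
#' Pearson correlation between a site's standardized profile and the
#' centroid (mean profile) of a kinase's known substrates, mapped to
#' \[0, 1\] as `(r + 1) / 2`. A zero-variance profile has no defined
#' correlation and scores `NA`.
#'
#' @param site_profile numeric vector over >= 2 conditions/contrasts.
#' @param known_profiles matrix (substrates x conditions) of known-substrate
#'   profiles, or a precomputed centroid vector.
#' @return profile score in \[0, 1\], or `NA`.
#' @export
profile_score <- function(site_profile, known_profiles) {
  centroid <- if (is.matrix(known_profiles)) colMeans(known_profiles)
              else known_profiles
  if (length(site_profile) != length(centroid) || length(centroid) < 2)
    stop("profiles must share >= 2 conditions")
  if (stats::sd(site_profile) == 0 || stats::sd(centroid) == 0)
    return(NA_real_)
  (stats::cor(site_profile, centroid) + 1) / 2
}

#' Combine motif and profile scores
#'
#' Weighted geometric mean `S_motif^w * S_profile^(1 - w)`.
#'
#' @param s_motif,s_profile component scores in \[0, 1\].
#' @param w motif weight in \[0, 1\].
#' @return combined score in \[0, 1\].
#' @export
combined_score <- function(s_motif, s_profile, w = 0.5) {
  stopifnot(w >= 0, w <= 1)
  s_motif^w * s_profile^(1 - w)
}

#' Score every (site, kinase) pair from motif and profile evidence
#'
#' For each kinase with at least `min_known` annotated substrates present in
#' both the window table and the profile matrix: builds the kinase's PSSM
#' and known-substrate centroid, then scores every quantified site. Known
#' substrates are included and flagged. Kinases below `min_known` are
#' skipped (recorded in `attr(, "skipped")`).
#'
#' @param windows data.frame with columns `site`, `window`.
#' @param profiles features x conditions matrix of standardized profiles
#'   (e.g. the output of [standardize()]).
#' @param annotation data.frame (kinase, site) of known substrates.
#' @param min_known minimum known substrates per eligible kinase.
#' @param w motif weight for [combined_score()].
#' @param alpha PSSM pseudocount.
#' @return data.frame: site, kinase, s_motif, s_profile, s_combined, known.
#' @export
score_all <- function(windows, profiles, annotation, min_known = 5,
                      w = 0.5, alpha = 0.01) {
  if (nrow(annotation) == 0) stop("empty annotation")
  win <- stats::setNames(windows$window, windows$site)
  sites <- intersect(windows$site, rownames(profiles))
  sets <- split(annotation$site, annotation$kinase)
  sets <- lapply(sets, intersect, sites)
  skipped <- names(sets)[lengths(sets) < min_known]
  sets <- sets[lengths(sets) >= min_known]
  out <- lapply(names(sets), function(k) {
    known <- sets[[k]]
    pssm <- build_pssm(win[known], alpha = alpha, min_known = min_known)
    centroid <- colMeans(profiles[known, , drop = FALSE])
    sm <- vapply(sites, function(s) motif_score(pssm, win[[s]]), numeric(1))
    sp <- vapply(sites, function(s)
      profile_score(profiles[s, ], centroid), numeric(1))
    data.frame(site = sites, kinase = k, s_motif = sm, s_profile = sp,
               s_combined = combined_score(sm, sp, w),
               known = sites %in% known,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  attr(res, "skipped") <- skipped
  res
}

#' Build a signalome network of kinases sharing predicted substrates
#'
#' Each site is assigned to its argmax-scoring kinase when that score
#' reaches `assign_threshold` (ties broken lexicographically and logged).
#' For an edge, each kinase's substrate-protein set is taken from the sites
#' on which it is among the top scorers with score >= threshold; the edge
#' weight between two kinases is the number of distinct proteins shared by
#' their sets. Zero-weight pairs are omitted.
#'
#' @param table a [score_all()] table.
#' @param assign_threshold minimum combined score for assignment.
#' @param site2protein named character vector site -> protein; by default
#'   the protein is the site id with its trailing `_<residue><pos>`
#'   stripped.
#' @return list with `assignments` (site, kinase, score), `edges`
#'   (kinase1, kinase2, weight) and `ties` (sites with tied argmax).
#' @export
build_signalome <- function(table, assign_threshold = 0.5,
                            site2protein = NULL) {
  sites <- unique(table$site)
  if (is.null(site2protein))
    site2protein <- stats::setNames(sub("_[STY][0-9]+$", "", sites), sites)
  kin <- sort(unique(table$kinase))
  smat <- matrix(NA_real_, length(sites), length(kin),
                 dimnames = list(sites, kin))
  smat[cbind(match(table$site, sites), match(table$kinase, kin))] <-
    table$s_combined
  best <- apply(smat, 1, max, na.rm = TRUE)
  assigned <- best >= assign_threshold
  ties <- character(0)
  pick <- vapply(seq_along(sites), function(i) {
    tops <- kin[which(!is.na(smat[i, ]) & smat[i, ] == best[i])]
    if (length(tops) > 1) ties <<- c(ties, sites[i])
    sort(tops)[1]
  }, character(1))
  assignments <- data.frame(site = sites[assigned],
                            kinase = pick[assigned],
                            score = best[assigned],
                            stringsAsFactors = FALSE, row.names = NULL)
  # per kinase: proteins of sites where it is (jointly) top-scoring above
  # the threshold
  prot_sets <- lapply(kin, function(k) {
    top <- !is.na(smat[, k]) & smat[, k] == best & smat[, k] >= assign_threshold
    unique(site2protein[sites[top]])
  })
  names(prot_sets) <- kin
  edges <- NULL
  if (length(kin) >= 2) {
    pairs <- utils::combn(sort(kin), 2)
    wts <- apply(pairs, 2, function(p)
      length(intersect(prot_sets[[p[1]]], prot_sets[[p[2]]])))
    edges <- data.frame(kinase1 = pairs[1, ], kinase2 = pairs[2, ],
                        weight = wts, stringsAsFactors = FALSE)
    edges <- edges[edges$weight > 0, , drop = FALSE]
    rownames(edges) <- NULL
  }
  list(assignments = assignments, edges = edges, ties = unique(ties))
}

#' Dissect inhibitor-specific substrates of two kinase groups
#'
#' Candidate sites are those whose prediction score for either kinase group
#' (group score = max over member kinases) exceeds `score_threshold`.
#' Candidates are then partitioned by their inhibition profile: more
#' inhibited under the first group's inhibitor (z on the first axis below z
#' on the second) makes the site specific to the first group, and vice
#' versa; ties are left unassigned, and candidates lacking an inhibition
#' value are excluded. Both the tie and exclusion lists are returned.
#'
#' @param table a [score_all()] table.
#' @param zmat_inhibition features x 2 z-matrix; first column the first
#'   group's inhibitor contrast (e.g. PD), second the other (e.g. SP).
#' @param kinase_groups named list of two character vectors of kinase ids,
#'   e.g. `list("MAPK1/3" = c("MAPK1", "MAPK3"), "MAPK8/9" = ...)`. The
#'   first group pairs with the first z column.
#' @param score_threshold combined-score cutoff (candidates must exceed it).
#' @return data.frame: site, group, S_combined, z_1, z_2 (columns named
#'   after the z-matrix axes), with attributes `unassigned` and `excluded`.
#' @export
dissect_specificity <- function(table, zmat_inhibition, kinase_groups,
                                score_threshold = 0.7) {
  stopifnot(length(kinase_groups) == 2, ncol(zmat_inhibition) == 2)
  grp_score <- function(members) {
    sub <- table[table$kinase %in% members, , drop = FALSE]
    if (nrow(sub) == 0) return(stats::setNames(numeric(0), character(0)))
    tapply(sub$s_combined, sub$site, max)
  }
  g1 <- grp_score(kinase_groups[[1]])
  g2 <- grp_score(kinase_groups[[2]])
  all_sites <- union(names(g1), names(g2))
  score <- pmax(g1[all_sites], g2[all_sites], na.rm = TRUE)
  names(score) <- all_sites
  cand <- all_sites[!is.na(score) & score > score_threshold]
  has_z <- cand %in% rownames(zmat_inhibition) &
    !is.na(rowSums(zmat_inhibition[match(cand, rownames(zmat_inhibition)), ,
                                   drop = FALSE]))
  excluded <- cand[!has_z]
  cand <- cand[has_z]
  z1 <- zmat_inhibition[cand, 1]
  z2 <- zmat_inhibition[cand, 2]
  group <- ifelse(z1 < z2, names(kinase_groups)[1],
                  ifelse(z2 < z1, names(kinase_groups)[2], NA_character_))
  res <- data.frame(site = cand, group = group,
                    S_combined = as.numeric(score[cand]),
                    z1 = as.numeric(z1), z2 = as.numeric(z2),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(res)[4:5] <- paste0("z_", colnames(zmat_inhibition))
  attr(res, "unassigned") <- cand[is.na(group)]
  attr(res, "excluded") <- excluded
  res
}
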