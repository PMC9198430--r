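#' Z-transform temporal fold-change profiles
#'
#' Per feature, subtracts the mean and divides by the sd across time points,
#' so clustering sees shape, not amplitude. Zero-sd (flat) features are
#' dropped and recorded in `attr(, "dropped")`.
#'
#' @param fc features x time-points matrix of log2 fold changes.
#' @return z-profile matrix (rows: mean 0, sd 1).
#' @export
ztransform_profiles <- function(fc) {
  if (ncol(fc) < 3) stop("need >= 3 time points")
  sds <- apply(fc, 1, stats::sd)
  dropped <- rownames(fc)[sds == 0]
  keep <- fc[sds > 0, , drop = FALSE]
  z <- (keep - rowMeans(keep)) / apply(keep, 1, stats::sd)
  attr(z, "dropped") <- dropped
  z
}

#' Fisher enrichment of a term in a cluster
#'
#' One-sided (enrichment) hypergeometric p-value on the 2x2 table of
#' cluster membership vs term membership over a universe; the odds ratio is
#' computed from the table, with the Haldane half-count correction when any
#' cell is zero.
#'
#' @param members feature ids in the cluster.
#' @param term feature ids carrying the annotation term.
#' @param universe all feature ids considered.
#' @return list with `odds_ratio`, `p` and the table counts `a`, `b`, `c`,
#'   `d`.
#' @export
fisher_enrichment <- function(members, term, universe) {
  if (length(setdiff(members, universe)) > 0 ||
      length(setdiff(term, universe)) > 0)
    stop("members and term must be subsets of the universe")
  a <- length(intersect(members, term))
  b <- length(members) - a
  cc <- length(term) - a
  d <- length(universe) - a - b - cc
  p <- stats::phyper(a - 1, length(term), length(universe) - length(term),
                     length(members), lower.tail = FALSE)
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  list(odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       p = p, a = a, b = b, c = cc, d = d)
}

enrichment_score <- function(membership, terms, alpha,
                             mode = c("sumlog", "count")) {
  mode <- match.arg(mode)
  universe <- names(membership)
  term_sets <- split(terms$feature, terms$term)
  term_sets <- lapply(term_sets, intersect, universe)
  term_sets <- term_sets[lengths(term_sets) > 0]
  total <- 0
  hits <- NULL
  for (cl in sort(unique(membership))) {
    members <- universe[membership == cl]
    p <- vapply(term_sets, function(ts)
      fisher_enrichment(members, ts, universe)$p, numeric(1))
    q <- bh_adjust(p)
    sig <- which(q <= alpha)
    if (length(sig) > 0) {
      total <- total + if (mode == "sumlog") sum(-log10(p[sig]))
                       else length(sig)
      hits <- rbind(hits, data.frame(cluster = cl,
                                     term = names(term_sets)[sig],
                                     p = p[sig], q = q[sig],
                                     stringsAsFactors = FALSE))
    }
  }
  list(score = total, hits = hits)
}

#' Enrichment-guided sweep over cluster numbers
#'
#' For each k in `k_range`, runs k-means with `n_starts` seeded restarts
#' (best within-cluster sum of squares kept) and computes the enrichment
#' score E(k): the sum over clusters and annotation terms of -log10 p for
#' terms reaching BH q <= `alpha` within the cluster (0 when none). The
#' optimal k* maximizes E(k), ties going to the smallest k. If no term is
#' enriched at any k a warning is issued.
#'
#' @param z z-profile matrix from [ztransform_profiles()].
#' @param k_range candidate cluster numbers, within \[2, n_features / 5\].
#' @param terms data.frame with columns `term`, `feature`.
#' @param n_starts k-means restarts per k.
#' @param alpha BH significance level inside E(k).
#' @param score_mode `"sumlog"` (default) or `"count"` of significant terms.
#' @param seed integer seed.
#' @return list of class `ClusterResult`: `k_tried`, `E` (named scores),
#'   `k_star`, `membership` (for k*), `memberships` (all k), `enriched`
#'   (terms at k*), `withinss` (best total within-SS per k).
#' @export
cluster_sweep <- function(z, k_range = 2:12, terms, n_starts = 20,
                          alpha = 0.05, score_mode = "sumlog", seed = 1) {
  if (is.null(terms) || nrow(terms) == 0) stop("empty annotation")
  if (min(k_range) < 2 || max(k_range) > nrow(z) / 5)
    stop("k_range must lie within [2, n_features / 5]")
  memberships <- list()
  E <- stats::setNames(numeric(length(k_range)), k_range)
  wss <- stats::setNames(numeric(length(k_range)), k_range)
  hits_by_k <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    best <- NULL
    for (r in seq_len(n_starts)) {
      set.seed(seed + 1000L * k + r)
      km <- stats::kmeans(z, centers = k, iter.max = 50)
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    membership <- stats::setNames(best$cluster, rownames(z))
    memberships[[as.character(k)]] <- membership
    es <- enrichment_score(membership, terms, alpha, score_mode)
    E[i] <- es$score
    wss[i] <- best$tot.withinss
    hits_by_k[[as.character(k)]] <- es$hits
  }
  k_star <- k_range[which.max(E)]  # which.max takes the first (smallest k)
  if (max(E) == 0)
    warning("no enrichment at any k; optimal k is not meaningful")
  structure(list(k_tried = k_range, E = E, k_star = k_star,
                 membership = memberships[[as.character(k_star)]],
                 memberships = memberships,
                 enriched = hits_by_k[[as.character(k_star)]],
                 withinss = wss),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: k tried %s; k* = %d (E = %.2f)\n",
              paste(range(x$k_tried), collapse = "-"), x$k_star,
              max(x$E)))
  invisible(x)
}

#' Mean z-profile per cluster
#'
#' @param z z-profile matrix.
#' @param membership named cluster assignment (from [cluster_sweep()]).
#' @return clusters x time-points matrix of mean profiles.
#' @export
cluster_centroids <- function(z, membership) {
  z <- z[names(membership), , drop = FALSE]
  rs <- rowsum(z, membership)
  rs / as.numeric(table(membership)[rownames(rs)])
}

#' Order temporal events from cluster mean profiles
#'
#' A cluster's direction is up when its maximum occurs after its minimum,
#' down otherwise. Its event time is the first time the mean profile crosses
#' the half-amplitude level (midpoint of its min and max), located by linear
#' interpolation between adjacent time points. Clusters are ranked by event
#' time (ties broken by cluster id order); flat profiles are excluded and
#' recorded in `attr(, "excluded")`.
#'
#' @param centroids clusters x time-points matrix (e.g.
#'   [cluster_centroids()]).
#' @param times numeric time coordinates, one per column.
#' @return data.frame of class `EventTable`: cluster, direction,
#'   event_time, rank.
#' @export
event_times <- function(centroids, times) {
  stopifnot(ncol(centroids) == length(times), !is.unsorted(times))
  excluded <- character(0)
  rows <- list()
  for (i in seq_len(nrow(centroids))) {
    prof <- centroids[i, ]
    cl <- rownames(centroids)[i]
    if (max(prof) - min(prof) < 1e-12) {
      excluded <- c(excluded, cl)
      next
    }
    dir <- if (times[which.max(prof)] > times[which.min(prof)]) "up" else "down"
    mid <- (max(prof) + min(prof)) / 2
    ev <- NA_real_
    for (j in seq_len(length(times) - 1)) {
      p1 <- prof[j]; p2 <- prof[j + 1]
      if (p1 == mid) { ev <- times[j]; break }
      if ((p1 - mid) * (p2 - mid) < 0 ||
          (p2 == mid && p1 != mid)) {
        ev <- times[j] + (mid - p1) / (p2 - p1) * (times[j + 1] - times[j])
        break
      }
    }
    rows[[cl]] <- data.frame(cluster = cl, direction = dir, event_time = ev,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$event_time, out$cluster), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("EventTable", "data.frame")
  out
}
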