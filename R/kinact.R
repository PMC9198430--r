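#' Standardize ratio profiles into a contrast z-matrix
#'
#' For each contrast (a non-reference condition of a ratio-scale matrix),
#' the feature value is its mean log2 ratio over that condition's
#' replicates; each contrast column is then centered and scaled to unit
#' sample sd across features, giving the standardized scores all set-level
#' statistics operate on.
#'
#' @param ratios ratio-scale `QuantMatrix`.
#' @param contrasts named character vector: contrast label -> condition
#'   label. Defaults to every non-reference condition, labelled
#'   `"<cond>-vs-<ref>"` when the reference is known.
#' @return numeric matrix (features x contrasts) of z-scores; per column,
#'   mean 0 and sample sd 1.
#' @export
standardize <- function(ratios, contrasts = NULL) {
  stopifnot(inherits(ratios, "QuantMatrix"))
  if (ratios$scale != "ratio") stop("standardize expects a ratio matrix")
  if (is.null(contrasts)) {
    ref <- attr(ratios, "reference")
    conds <- setdiff(levels(ratios$design$condition), ref)
    contrasts <- stats::setNames(conds, if (is.null(ref)) conds
                                 else paste0(conds, "-vs-", ref))
  }
  bad <- setdiff(contrasts, levels(ratios$design$condition))
  if (length(bad) > 0)
    stop("contrast condition(s) not in design: ", paste(bad, collapse = ", "))
  z <- vapply(contrasts, function(cc)
    rowMeans(ratios$values[, ratios$design$condition == cc, drop = FALSE]),
    numeric(nrow(ratios$values)))
  if (nrow(ratios$values) == 1) z <- matrix(z, nrow = 1)
  dimnames(z) <- list(rownames(ratios$values), names(contrasts))
  sds <- apply(z, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance contrast column(s): ",
         paste(colnames(z)[sds == 0], collapse = ", "))
  scale(z, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Stouffer set test on one contrast axis
#'
#' Combines the standardized scores of a feature set into
#' `Z = sum(z_i) / sqrt(n)` with a two-sided normal p-value. Under the null
#' (members exchangeable with the standard-normal background) Z is standard
#' normal, so |Z| measures coordinated change of the set -- the substrate-set
#' statistic behind kinase-activity inference.
#'
#' @param z named numeric vector of per-feature scores for one axis.
#' @param members feature ids of the set (must be present in `z`).
#' @return list with `Z`, `p` and `n`.
#' @export
stouffer_set_test <- function(z, members) {
  if (length(members) == 0) stop("empty member set")
  missing <- setdiff(members, names(z))
  if (length(missing) > 0)
    stop("members absent from scores: ", paste(missing, collapse = ", "))
  zi <- z[members]
  Z <- sum(zi) / sqrt(length(zi))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)), n = length(zi))
}

#' Construct a unit direction in contrast space
#'
#' @param v numeric vector over contrast axes (length 2 or 3); normalized to
#'   unit Euclidean norm.
#' @param label human-readable label.
#' @return a `Direction`: the unit vector with attribute `label`.
#' @export
direction <- function(v, label = NULL) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("zero direction vector")
  u <- v / nrm
  if (is.null(label)) label <- paste(round(u, 3), collapse = ",")
  structure(u, label = label, class = "Direction")
}

#' Canonical inhibition directions in the (PD, SP) plane
#'
#' Eight unit vectors at 45-degree steps. Contrasts are log2(treated /
#' control), so "inhibited" means negative: "inhibited by PD only" is
#' (-1, 0), "inhibited by SP only" is (0, -1), "inhibited by both" is
#' (-1/sqrt(2), -1/sqrt(2)).
#'
#' @param axes contrast labels for the two axes (PD first).
#' @return named list of `Direction` objects.
#' @export
canonical_directions <- function(axes = c("PD", "SP")) {
  stopifnot(length(axes) == 2)
  lab <- function(dx, dy) {
    part <- function(d, ax) {
      if (d > 0.01) paste0("up in ", ax)
      else if (d < -0.01) paste0("inhibited by ", ax)
      else NULL
    }
    p <- c(part(dx, axes[1]), part(dy, axes[2]))
    if (length(p) == 2) {
      if (grepl("^inhibited", p[1]) && grepl("^inhibited", p[2]))
        return("inhibited by both")
      if (grepl("^up", p[1]) && grepl("^up", p[2])) return("up in both")
      return(paste(p, collapse = ", "))
    }
    paste0(p, " only")
  }
  angles <- seq(0, 315, by = 45) * pi / 180
  dirs <- lapply(angles, function(a) {
    v <- c(cos(a), sin(a))
    v[abs(v) < 1e-12] <- 0
    direction(v, label = lab(v[1], v[2]))
  })
  names(dirs) <- vapply(dirs, attr, character(1), "label")
  dirs
}

#' Project standardized scores onto a direction
#'
#' Dot product of each feature's z-vector with a unit direction; under
#' independent standard-normal columns the projected scores are again
#' standard normal, so they feed directly into [stouffer_set_test()].
#'
#' @param zmat features x contrasts z-matrix, restricted to the direction's
#'   axes (2 or 3 columns).
#' @param dir a [direction()].
#' @return named numeric vector of projected scores.
#' @export
project <- function(zmat, dir) {
  if (ncol(zmat) != length(dir))
    stop("direction length does not match number of contrast axes")
  if (abs(sqrt(sum(dir^2)) - 1) > 1e-9) stop("direction must be unit norm")
  drop(zmat %*% as.numeric(dir))
}

#' Direction-based kinase analysis of paired inhibitor contrasts
#'
#' For each kinase and each direction: project the z-matrix onto the
#' direction and apply the Stouffer set test over the kinase's known
#' substrates. p-values are BH-adjusted across kinases within each
#' direction. Kinases with fewer than `min_substrates` quantified substrates
#' are excluded (recorded in `attr(, "excluded")`).
#'
#' @param zmat features x contrasts z-matrix (2-3 columns, e.g. PD and SP).
#' @param annotation data.frame (kinase, site) of known substrates.
#' @param directions list of [direction()]s; defaults to
#'   [canonical_directions()] on the matrix's column names.
#' @param min_substrates minimum quantified substrates per kinase.
#' @return data.frame: kinase, direction, n, Z, p, q.
#' @export
kinase_direction_analysis <- function(zmat, annotation, directions = NULL,
                                      min_substrates = 3) {
  if (is.null(directions)) directions <- canonical_directions(colnames(zmat))
  sets <- split(annotation$site, annotation$kinase)
  sets <- lapply(sets, intersect, rownames(zmat))
  excluded <- names(sets)[lengths(sets) < min_substrates]
  sets <- sets[lengths(sets) >= min_substrates]
  if (length(sets) == 0) stop("no kinase has enough quantified substrates")
  res <- do.call(rbind, lapply(names(directions), function(dl) {
    sc <- project(zmat, directions[[dl]])
    rows <- lapply(names(sets), function(k) {
      st <- stouffer_set_test(sc, sets[[k]])
      data.frame(kinase = k, direction = dl, n = st$n, Z = st$Z, p = st$p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- bh_adjust(out$p)
    out
  }))
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Kinase activity inference over time contrasts
#'
#' Per (kinase, time contrast), the Stouffer set test over the kinase's
#' known substrates; the signed Z is reported as the inferred activity.
#' BH adjustment is across kinases within each contrast.
#'
#' @param zmat features x time-contrasts z-matrix.
#' @param annotation data.frame (kinase, site).
#' @param min_substrates minimum quantified substrates per kinase.
#' @return data.frame: kinase, contrast, n, Z, p, q; excluded kinases in
#'   `attr(, "excluded")`.
#' @export
kinase_activity_timecourse <- function(zmat, annotation,
                                       min_substrates = 3) {
  sets <- split(annotation$site, annotation$kinase)
  sets <- lapply(sets, intersect, rownames(zmat))
  excluded <- names(sets)[lengths(sets) < min_substrates]
  sets <- sets[lengths(sets) >= min_substrates]
  if (length(sets) == 0) stop("no kinase has enough quantified substrates")
  res <- do.call(rbind, lapply(colnames(zmat), function(ct) {
    zc <- stats::setNames(zmat[, ct], rownames(zmat))
    rows <- lapply(names(sets), function(k) {
      st <- stouffer_set_test(zc, sets[[k]])
      data.frame(kinase = k, contrast = ct, n = st$n, Z = st$Z, p = st$p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- bh_adjust(out$p)
    out
  }))
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}
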