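#' Gate cells on marker expression
#'
#' Keeps cells where any positive marker exceeds the threshold AND every
#' negative marker is at or below it -- e.g. the progenitor/myotube gate
#' `(Myf5+ or Myod1+) and Myog-`.
#'
#' @param expr cells x genes numeric matrix (counts).
#' @param positive marker genes, any of which must be expressed.
#' @param negative marker genes, all of which must be absent.
#' @param threshold expression threshold (default 0: "> 0 counts").
#' @return character vector of gated-in cell ids.
#' @export
gate_cells <- function(expr, positive = c("Myf5", "Myod1"),
                       negative = "Myog", threshold = 0) {
  if (length(intersect(positive, negative)) > 0)
    stop("positive and negative marker sets must be disjoint")
  missing <- setdiff(c(positive, negative), colnames(expr))
  if (length(missing) > 0)
    stop("markers absent from gene list: ", paste(missing, collapse = ", "))
  pos_ok <- rowSums(expr[, positive, drop = FALSE] > threshold) > 0
  neg_ok <- rowSums(expr[, negative, drop = FALSE] > threshold) == 0
  rownames(expr)[pos_ok & neg_ok]
}

#' Drop genes dominated by zeros
#'
#' Keeps genes whose zero fraction is at most `max_zero_fraction` (a gene
#' with strictly more zeros is dropped).
#'
#' @param expr cells x genes matrix.
#' @param max_zero_fraction maximum tolerated zero fraction.
#' @return character vector of retained gene ids.
#' @export
filter_sparse_genes <- function(expr, max_zero_fraction = 0.95) {
  zf <- colMeans(expr == 0)
  colnames(expr)[zf <= max_zero_fraction]
}

#' Top highly variable genes
#'
#' Ranks genes by the variance of log1p-transformed expression and returns
#' the top `n`; ties are broken by gene id order.
#'
#' @param expr cells x genes matrix.
#' @param n number of genes.
#' @return character vector of gene ids.
#' @export
top_hvg <- function(expr, n = 100) {
  v <- apply(log1p(expr), 2, stats::var)
  ord <- order(-v, colnames(expr))
  colnames(expr)[ord[seq_len(min(n, ncol(expr)))]]
}

#' Correlate single-cell transcriptomes with proteome time points
#'
#' Pearson correlation between each cell's expression vector and each time
#' point's protein ratio vector over the shared (HVG) genes; gene pairs with
#' missing values are dropped pairwise.
#'
#' @param expr cells x genes matrix restricted to HVGs (any monotone
#'   transform; Pearson is computed on the values given).
#' @param proteome genes x time-points matrix of protein ratios, rownames
#'   matching gene symbols.
#' @return cells x time-points correlation matrix.
#' @export
correlate_cells_to_timepoints <- function(expr, proteome) {
  shared <- intersect(colnames(expr), rownames(proteome))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  stats::cor(t(expr[, shared, drop = FALSE]),
             proteome[shared, , drop = FALSE],
             use = "pairwise.complete.obs")
}

#' Nuclei/myotube count summary
#'
#' @param total_nuclei total nuclei counted.
#' @param nuclei_in_mhc nuclei within MHC+ cells.
#' @param mhc_cells MHC+ cell count.
#' @param nuclei_in_myotubes nuclei within multinucleated (>= 4 nuclei)
#'   myotubes; tubes with fewer nuclei contribute nothing.
#' @return a validated `CountSummary` list.
#' @export
count_summary <- function(total_nuclei, nuclei_in_mhc, mhc_cells,
                          nuclei_in_myotubes) {
  v <- c(total_nuclei, nuclei_in_mhc, mhc_cells, nuclei_in_myotubes)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (total_nuclei == 0) stop("total nuclei must be positive")
  if (any(v[-1] > total_nuclei)) stop("component counts exceed total nuclei")
  structure(list(total_nuclei = total_nuclei, nuclei_in_mhc = nuclei_in_mhc,
                 mhc_cells = mhc_cells,
                 nuclei_in_myotubes = nuclei_in_myotubes),
            class = "CountSummary")
}

#' Morphology indices from stained-image counts
#'
#' Differentiation index = nuclei within MHC+ cells / total nuclei;
#' percentage of MHC+ cells = MHC+ cells / total nuclei; fusion index =
#' nuclei within multinucleated (>= 4) myotubes / total nuclei.
#'
#' @param counts a [count_summary()].
#' @return named numeric vector: differentiation_index, pct_mhc_positive,
#'   fusion_index.
#' @export
morphology_indices <- function(counts) {
  stopifnot(inherits(counts, "CountSummary"))
  c(differentiation_index = counts$nuclei_in_mhc / counts$total_nuclei,
    pct_mhc_positive = counts$mhc_cells / counts$total_nuclei,
    fusion_index = counts$nuclei_in_myotubes / counts$total_nuclei)
}
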