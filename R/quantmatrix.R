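#' Quantification matrix with sample design
#'
#' The central container of the package: a features x samples matrix of
#' log2-scale values (LFQ-style intensities or ratios relative to a
#' reference condition) together with a per-sample design describing
#' condition, replicate and batch. Missing quantifications are `NA`.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Rownames are feature ids, colnames sample ids; both required.
#' @param design data.frame with columns `sample`, `condition`, `replicate`,
#'   `batch`, one row per column of `values`, in the same order or keyed by
#'   `sample`. The order of `condition` levels (factor levels, or first
#'   appearance) defines the time ordering used by adjacency filters.
#' @param scale either `"intensity"` or `"ratio"`.
#'
#' @return An object of class `QuantMatrix`: a list with elements `values`,
#'   `design` (with `condition` as a factor whose level order is the declared
#'   time order) and `scale`.
#' @export
quant_matrix <- function(values, design, scale = c("intensity", "ratio")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  req <- c("sample", "condition", "replicate", "batch")
  if (!all(req %in% names(design)))
    stop("design must have columns: ", paste(req, collapse = ", "))
  design <- as.data.frame(design)
  unmatched <- c(setdiff(colnames(values), design$sample),
                 setdiff(design$sample, colnames(values)))
  if (length(unmatched) > 0)
    stop("sample ids in matrix and design do not match: ",
         paste(unmatched, collapse = ", "))
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  if (!is.factor(design$condition))
    design$condition <- factor(design$condition,
                               levels = unique(design$condition))
  design$batch <- as.character(design$batch)
  structure(list(values = values, design = design, scale = scale),
            class = "QuantMatrix")
}

#' @export
print.QuantMatrix <- function(x, ...) {
  cat(sprintf("QuantMatrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  conditions: %s\n",
              paste(levels(x$design$condition), collapse = ", ")))
  cat(sprintf("  batches: %s; missing cells: %d (%.1f%%)\n",
              paste(unique(x$design$batch), collapse = ", "),
              sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.QuantMatrix <- function(x) dim(x$values)

#' Number of missing cells in a QuantMatrix
#' @param m a `QuantMatrix`.
#' @return integer count of `NA` cells.
#' @export
n_missing <- function(m) sum(is.na(m$values))

#' Construct a factorial sample design
#'
#' Builds the sample design table for a conditions x replicates layout with
#' replicates split across batches (replicates are dealt to batches in
#' round-robin blocks, so e.g. 4 replicates over 2 batches puts replicates
#' 1-2 in the first batch and 3-4 in the second).
#'
#' @param conditions character vector of condition labels in time order;
#'   the first is the reference unless `reference` is given.
#' @param n_replicates replicates per condition.
#' @param n_batches number of batches.
#' @param reference reference condition label.
#' @return data.frame with columns sample, condition, replicate, batch and
#'   attribute `reference`.
#' @export
make_design <- function(conditions, n_replicates = 4, n_batches = 2,
                        reference = conditions[1]) {
  stopifnot(length(conditions) >= 1, n_replicates >= 1, n_batches >= 1)
  if (!reference %in% conditions) stop("reference not among conditions")
  d <- expand.grid(replicate = seq_len(n_replicates),
                   condition = conditions, stringsAsFactors = FALSE)
  d <- d[, c("condition", "replicate")]
  batch_of_rep <- rep(LETTERS[seq_len(n_batches)],
                      each = ceiling(n_replicates / n_batches),
                      length.out = n_replicates)
  d$batch <- batch_of_rep[d$replicate]
  d$sample <- paste0(d$condition, "_r", d$replicate)
  d <- d[, c("sample", "condition", "replicate", "batch")]
  d$condition <- factor(d$condition, levels = conditions)
  attr(d, "reference") <- reference
  d
}

#' Read a quantification matrix and its design from TSV files
#'
#' The data file has feature ids in the first column and one column per
#' sample; empty fields are missing values. The design file has columns
#' sample, condition, replicate, batch. Sample ids must match exactly.
#'
#' @param path path to the features x samples TSV.
#' @param design_path path to the design TSV.
#' @param scale `"intensity"` or `"ratio"`.
#' @return a `QuantMatrix`.
#' @export
read_quant_matrix <- function(path, design_path,
                              scale = c("intensity", "ratio")) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                           colClasses = "character")
  if (ncol(raw) < 2) stop("quantification file needs id + sample columns")
  ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("malformed numeric cell at feature '%s', sample '%s': '%s'",
                 ids[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]))
  rownames(num) <- ids
  design <- utils::read.delim(design_path, check.names = FALSE)
  quant_matrix(num, design, scale = scale)
}

#' Write a QuantMatrix (and optionally its design) to TSV
#'
#' @param m a `QuantMatrix`.
#' @param path output path for the features x samples TSV.
#' @param design_path optional output path for the design TSV.
#' @return `m`, invisibly.
#' @export
write_quant_matrix <- function(m, path, design_path = NULL) {
  stopifnot(inherits(m, "QuantMatrix"))
  df <- data.frame(feature = rownames(m$values), m$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  if (!is.null(design_path))
    utils::write.table(m$design, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(m)
}
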