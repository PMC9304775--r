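#' Per-cell quality-control metrics
#'
#' Computes, for every cell library, the number of detected genes
#' (count > 0), the total count, and the fraction of counts assigned to
#' mitochondrial genes (0 for empty cells, which are flagged degenerate).
#'
#' @param m a [count_matrix()].
#' @return data.frame of class `cell_qc` with columns `cell_id`,
#'   `genes_detected`, `total_counts`, `mito_proportion`, `degenerate`,
#'   `excluded_manually`.
#' @export
compute_cell_qc <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (ncol(m$counts) == 0) stop("empty count matrix", call. = FALSE)
  total <- Matrix::colSums(m$counts)
  detected <- Matrix::colSums(m$counts > 0)
  mito <- m$gene_flags$mito
  if (!any(mito)) {
    warning("no mitochondrial genes flagged; mito_proportion set to 0")
    mprop <- rep(0, ncol(m$counts))
  } else {
    msum <- Matrix::colSums(m$counts[mito, , drop = FALSE])
    mprop <- ifelse(total > 0, msum / total, 0)
  }
  structure(data.frame(cell_id = cell_ids(m),
                       genes_detected = as.integer(detected),
                       total_counts = total,
                       mito_proportion = mprop,
                       degenerate = total == 0,
                       excluded_manually = m$cell_meta$excluded_manually,
                       row.names = NULL),
            class = c("cell_qc", "data.frame"))
}

#' MAD-based outlier filter over cells
#'
#' A cell is dropped iff its detected-gene count lies more than
#' `n_mads` median absolute deviations from the median (both tails), or
#' its mitochondrial proportion exceeds the median by more than `n_mads`
#' MADs (upper tail only: only high mitochondrial content is
#' pathological). The MAD uses the 1.4826 normal-consistency constant by
#' default. A zero MAD on a metric disables outlier calls on that metric
#' (a constant metric should not drop everything). Manually excluded
#' cells are always dropped.
#'
#' @param q a `cell_qc` data.frame from [compute_cell_qc()].
#' @param n_mads cutoff in MAD units (default 3).
#' @param genes_detected_two_sided,mito_upper_only tail configuration.
#' @param consistency MAD scale constant (1.4826, or 1 for the raw MAD).
#' @return logical keep-mask over cells.
#' @export
mad_outlier_filter <- function(q, n_mads = 3, genes_detected_two_sided = TRUE,
                               mito_upper_only = TRUE, consistency = 1.4826) {
  stopifnot(inherits(q, "cell_qc"), n_mads > 0)
  if (nrow(q) < 2) stop("need at least 2 cells", call. = FALSE)
  out_g <- mad_flags(q$genes_detected, n_mads, consistency,
                     lower = TRUE, upper = genes_detected_two_sided)
  out_m <- mad_flags(q$mito_proportion, n_mads, consistency,
                     lower = !mito_upper_only, upper = TRUE)
  keep <- !(out_g | out_m)
  keep[q$excluded_manually] <- FALSE
  keep
}

mad_flags <- function(x, n_mads, consistency, lower, upper) {
  med <- stats::median(x)
  m <- stats::mad(x, constant = consistency)
  if (m == 0) return(rep(FALSE, length(x)))
  dev <- x - med
  (lower & dev < -n_mads * m) | (upper & dev > n_mads * m)
}

#' Detection-threshold gene filter
#'
#' Drops all-zero genes and keeps a gene iff it has at least `min_count`
#' counts in at least `min_cells` cells. With `quartile_filter`,
#' additionally restricts to the top 25% of survivors by mean expression.
#'
#' @param m a [count_matrix()].
#' @param min_count per-cell count threshold (default 10).
#' @param min_cells number of cells required at that threshold (default 3).
#' @param quartile_filter keep only the fourth quartile of mean expression
#'   among survivors (default FALSE).
#' @return logical keep-mask over genes.
#' @export
filter_genes <- function(m, min_count = 10, min_cells = 3,
                         quartile_filter = FALSE) {
  stopifnot(inherits(m, "count_matrix"))
  if (min_cells > ncol(m$counts))
    stop("min_cells exceeds the number of cells", call. = FALSE)
  keep <- Matrix::rowSums(m$counts >= min_count) >= min_cells &
    Matrix::rowSums(m$counts) > 0
  if (quartile_filter && any(keep)) {
    mu <- Matrix::rowMeans(m$counts)
    cut <- stats::quantile(mu[keep], 0.75)
    keep <- keep & mu >= cut
  }
  keep
}
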