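#' Pooled deconvolution size factors
#'
#' Estimates per-cell scaling factors by summing cells into overlapping
#' pools and deconvolving the pooled estimates, which dampens the
#' zero-inflation that defeats per-cell median-ratio estimators at
#' single-cell depth. Cells are placed on a ring ordered by library size;
#' for every pool size `k` and every window of `k` consecutive cells the
#' pooled count vector is compared to the average pseudo-cell (per-gene
#' mean over all cells) by the median of gene-wise ratios, giving one
#' linear equation `sum of the window's factors = pooled factor`. The
#' stacked system (plus weakly weighted per-cell library-size anchors that
#' make it full rank) is solved by least squares and the solution rescaled
#' to unit mean. Non-positive estimates are clipped to the smallest
#' positive one with a warning.
#'
#' @param m a [count_matrix()] (genes already filtered).
#' @param pool_sizes integer pool sizes; capped at half the cell count.
#' @param min_mean genes with pseudo-cell mean below this are ignored.
#' @param anchor_weight weight of the per-cell anchor equations.
#' @return object of class `size_factors`: `factor` (per cell, unit
#'   mean), `pool_sizes_used`, `rescaled_to_unit_mean`.
#' @export
deconvolution_size_factors <- function(m, pool_sizes = c(20, 40, 60, 80, 100),
                                       min_mean = 1, anchor_weight = 0.01) {
  stopifnot(inherits(m, "count_matrix"))
  n <- ncol(m$counts)
  pool_sizes <- sort(unique(pmin(pool_sizes, max(floor(n / 2), 1))))
  pool_sizes <- pool_sizes[pool_sizes >= 1]
  if (n < max(pool_sizes)) stop("fewer cells than largest pool", call. = FALSE)
  counts <- as.matrix(m$counts)
  pseudo <- rowMeans(counts)
  if (all(pseudo == 0)) stop("all-zero pseudo-cell", call. = FALSE)
  use <- pseudo >= min_mean
  if (!any(use)) stop("no genes reach min_mean in the pseudo-cell", call. = FALSE)
  counts <- counts[use, , drop = FALSE]
  pseudo <- pseudo[use]

  lib <- colSums(counts)
  ring <- order(lib)
  n_eq <- length(pool_sizes) * n + n
  ii <- vector("list", n_eq); bb <- numeric(n_eq)
  row <- 0L
  # cumulative sums along the doubled ring give O(1) window sums
  cs <- cbind(0, t(apply(counts[, c(ring, ring), drop = FALSE], 1, cumsum)))
  for (k in pool_sizes) {
    for (s in seq_len(n)) {
      row <- row + 1L
      pooled <- cs[, s + k] - cs[, s]
      bb[row] <- stats::median(pooled / pseudo)
      ii[[row]] <- ring[((s - 1L) + seq_len(k) - 1L) %% n + 1L]
    }
  }
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(length(pool_sizes) * n), lengths(ii[seq_len(row)])),
    j = unlist(ii[seq_len(row)]),
    x = 1, dims = c(row, n))
  # anchors: theta_c ~ library-size factor, weakly weighted
  anchor <- lib / mean(lib)
  A <- rbind(A, anchor_weight * Matrix::Diagonal(n))
  b <- c(bb[seq_len(row)], anchor_weight * anchor)
  theta <- as.vector(Matrix::solve(Matrix::crossprod(A),
                                   Matrix::crossprod(A, b)))
  if (any(theta <= 0)) {
    pos <- theta[theta > 0]
    if (!length(pos)) stop("all deconvolution factors non-positive", call. = FALSE)
    warning(sum(theta <= 0), " non-positive size factor(s) clipped")
    theta[theta <= 0] <- min(pos)
  }
  theta <- theta / mean(theta)
  structure(list(factor = theta, pool_sizes_used = pool_sizes,
                 rescaled_to_unit_mean = TRUE),
            class = "size_factors")
}

#' Library-size factors
#'
#' Plain total-count factors rescaled to unit mean; the degenerate
#' reference the deconvolution estimator reduces to when all cells share
#' one composition.
#'
#' @param m a [count_matrix()].
#' @return a `size_factors` object.
#' @export
library_size_factors <- function(m) {
  lib <- Matrix::colSums(m$counts)
  if (any(lib == 0)) stop("cells with zero counts", call. = FALSE)
  structure(list(factor = lib / mean(lib), pool_sizes_used = integer(),
                 rescaled_to_unit_mean = TRUE),
            class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat(sprintf("size_factors for %d cells; range [%.3f, %.3f]; pools: %s\n",
              length(x$factor), min(x$factor), max(x$factor),
              if (length(x$pool_sizes_used))
                paste(x$pool_sizes_used, collapse = ",") else "library-size"))
  invisible(x)
}

#' Log2 counts-per-million expression values
#'
#' `value[g, c] = log2(count[g, c] / eff_lib_c * 1e6 + pseudocount)` with
#' effective library size `eff_lib_c = factor_c * mean(total counts)`, so
#' factors and CPM stay mutually consistent and CPM keeps its per-million
#' scale. A zero count maps to `log2(pseudocount)` (0 at the default).
#'
#' @param m a [count_matrix()].
#' @param sf a `size_factors` object aligned to the cells of `m`.
#' @param pseudocount positive offset on the CPM scale (default 1).
#' @return object of class `expression_matrix`: `values` (dense log2-CPM
#'   matrix), `cpm` (linear CPM), `pseudocount`, `size_factors`,
#'   `eff_lib`.
#' @export
log2_cpm <- function(m, sf, pseudocount = 1) {
  stopifnot(inherits(m, "count_matrix"), inherits(sf, "size_factors"))
  if (length(sf$factor) != ncol(m$counts))
    stop("size factors not aligned to cells", call. = FALSE)
  if (any(sf$factor <= 0)) stop("non-positive size factor", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  eff <- sf$factor * mean(Matrix::colSums(m$counts))
  cpm <- sweep(as.matrix(m$counts), 2, eff, "/") * 1e6
  structure(list(values = log2(cpm + pseudocount), cpm = cpm,
                 pseudocount = pseudocount, size_factors = sf,
                 eff_lib = eff),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (log2 CPM, pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
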