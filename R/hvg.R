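#' LOESS mean-variance trend and variance-ratio test
#'
#' Fits the per-gene variance of log2-CPM against the per-gene mean with
#' a robust local-linear LOESS (tricube weights). The fitted value is the
#' technical-variance expectation at that mean; each gene's ratio of
#' observed to fitted variance is tested one-sided against a scaled
#' chi-square model, `(n - 1) * variance / trend ~ chisq(n - 1)`, and
#' BH-adjusted. Constant genes get ratio 0 and p = 1.
#'
#' @param e an [log2_cpm()] `expression_matrix`.
#' @param span LOESS span (default 0.3).
#' @param trend_floor positive floor applied to the fitted trend.
#' @return data.frame of class `variance_fit`: `gene_id`, `mean`, `var`,
#'   `trend`, `ratio`, `p`, `fdr`; attribute `loess_span`.
#' @export
fit_variance_trend <- function(e, span = 0.3, trend_floor = 1e-8) {
  stopifnot(inherits(e, "expression_matrix"))
  v <- e$values
  if (nrow(v) < 20 || ncol(v) < 3)
    stop("need >= 20 genes and >= 3 cells", call. = FALSE)
  n <- ncol(v)
  mu <- rowMeans(v)
  va <- rowSums((v - mu)^2) / (n - 1)
  fit <- stats::loess(va ~ mu, span = span, degree = 1, family = "symmetric")
  trend <- pmax(stats::predict(fit, mu), trend_floor)
  ratio <- ifelse(va == 0, 0, va / trend)
  p <- ifelse(va == 0, 1,
              stats::pchisq((n - 1) * ratio, df = n - 1, lower.tail = FALSE))
  out <- data.frame(gene_id = rownames(v), mean = mu, var = va,
                    trend = trend, ratio = ratio, p = p,
                    fdr = stats::p.adjust(p, "BH"), row.names = NULL)
  attr(out, "loess_span") <- span
  class(out) <- c("variance_fit", "data.frame")
  out
}

#' Select highly variable genes from a variance fit
#'
#' Keeps genes whose variance deviates more than `fold`-fold from the
#' fitted trend at an FDR below `fdr_max`.
#'
#' @param f a `variance_fit`.
#' @param fold minimum variance ratio (default 2).
#' @param fdr_max FDR ceiling (default 0.05).
#' @return character vector of gene ids.
#' @export
select_variable_genes <- function(f, fold = 2, fdr_max = 0.05) {
  stopifnot(inherits(f, "variance_fit"))
  f$gene_id[f$ratio > fold & f$fdr < fdr_max]
}

#' Spearman correlation filter with a pooled permutation null
#'
#' Removes noisy candidates by requiring each retained gene to correlate
#' with at least one other candidate across cells. Spearman's rho (mid
#' ranks for ties) is computed for every candidate pair; p-values come
#' from one pooled permutation null (rho between two independently
#' shuffled rank vectors, shared across pairs), BH-adjusted across pairs.
#' A gene is kept iff it participates in a pair with `fdr <= fdr_max` and
#' `|rho| > rho_min`. Rank-based, so invariant to monotone per-gene
#' transforms.
#'
#' @param e an `expression_matrix`.
#' @param candidates gene ids to filter (>= 2).
#' @param rho_min,fdr_max gates (defaults 0.4 and 0.001).
#' @param n_perm permutation count (>= 100; default 10000).
#' @param seed integer seed for the permutation null.
#' @return object of class `correlation_result`: `pairs` (data.frame:
#'   gene_a, gene_b, rho, p, fdr), `kept_genes`, `n_perm`.
#' @export
correlation_filter <- function(e, candidates, rho_min = 0.4, fdr_max = 0.001,
                               n_perm = 10000, seed = 1L) {
  stopifnot(inherits(e, "expression_matrix"))
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  candidates <- intersect(candidates, rownames(e$values))
  if (length(candidates) < 2) stop("need >= 2 candidate genes", call. = FALSE)
  v <- e$values[candidates, , drop = FALSE]
  n <- ncol(v)
  rk <- t(apply(v, 1, rank))                 # mid-ranks
  rho <- stats::cor(t(rk))                   # Pearson on ranks = Spearman
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  obs <- abs(rho[idx])

  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    stats::cor(sample.int(n), sample.int(n)), numeric(1))
  null <- sort(abs(null))
  # p = (1 + #{|null| >= |obs|}) / (n_perm + 1)
  p <- (1 + n_perm - findInterval(obs - 1e-12, null)) / (n_perm + 1)
  fdr <- stats::p.adjust(p, "BH")

  pairs <- data.frame(gene_a = candidates[idx[, 1]],
                      gene_b = candidates[idx[, 2]],
                      rho = rho[idx], p = p, fdr = fdr)
  hit <- pairs$fdr <= fdr_max & abs(pairs$rho) > rho_min
  kept <- sort(unique(c(pairs$gene_a[hit], pairs$gene_b[hit])))
  structure(list(pairs = pairs, kept_genes = kept, n_perm = n_perm),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: %d pairs tested, %d genes kept (n_perm %d)\n",
              nrow(x$pairs), length(x$kept_genes), x$n_perm))
  invisible(x)
}
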