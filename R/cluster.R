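#' Median-center expression values
#'
#' Subtracts each gene's across-cell median from its log2-CPM values —
#' the quantity displayed on clustering heatmaps (difference from the
#' median CPM on the log2 fold-change scale) and the space in which cells
#' are clustered.
#'
#' @param e an `expression_matrix`.
#' @param genes gene ids to retain (nonempty subset of `e`).
#' @return object of class `centered_matrix` with element `values`.
#' @export
median_center <- function(e, genes = rownames(e$values)) {
  stopifnot(inherits(e, "expression_matrix"))
  genes <- intersect(genes, rownames(e$values))
  if (!length(genes)) stop("empty gene set", call. = FALSE)
  v <- e$values[genes, , drop = FALSE]
  med <- apply(v, 1, stats::median)
  structure(list(values = v - med), class = "centered_matrix")
}

#' Ward hierarchical clustering with a minimum cluster size
#'
#' Agglomerative clustering of cells with Ward linkage on Euclidean
#' distances over median-centered log2 CPM. Unless `k` is given, the tree
#' is cut at the largest number of clusters such that (a) every cluster
#' holds at least `min_cluster_size` cells (scanning cuts from high k
#' downward) and (b) the cut separates real structure: the ratio between
#' the merge height joining two of the k clusters and the tallest merge
#' inside them must reach `gap_min`. The guard stops the size rule from
#' slicing homogeneous groups into arbitrary noise subclusters (within a
#' homogeneous group Ward merge heights grow smoothly, ratio near 1;
#' between distinct populations the dendrogram jumps). A dataset with no
#' structure therefore yields a single cluster. Deterministic for a given
#' input.
#'
#' @param cm a [median_center()] `centered_matrix`.
#' @param min_cluster_size smallest admissible cluster (default 5).
#' @param gap_min minimum merge-height ratio for a cut to count as
#'   structure (default 1.3).
#' @param k optional fixed number of clusters for reproduction runs.
#' @return object of class `clustering_result`: `labels` (integer per
#'   cell, named), `linkage` (hclust), `genes_used`, `min_cluster_size`,
#'   `k`, `iterations` (empty here), `converged` (NA here).
#' @export
ward_cluster <- function(cm, min_cluster_size = 5, gap_min = 1.3, k = NULL) {
  stopifnot(inherits(cm, "centered_matrix"))
  n <- ncol(cm$values)
  if (is.null(k) && n < 2 * min_cluster_size) {
    warning("fewer cells than twice the minimum cluster size; single cluster")
    labels <- stats::setNames(rep(1L, n), colnames(cm$values))
    return(structure(list(labels = labels, linkage = NULL,
                          genes_used = rownames(cm$values),
                          min_cluster_size = min_cluster_size, k = 1L,
                          iterations = list(), converged = NA),
                     class = "clustering_result"))
  }
  hc <- stats::hclust(stats::dist(t(cm$values)), method = "ward.D2")
  if (is.null(k)) {
    h <- hc$height
    k <- 1L
    k_hi <- min(max(floor(n / min_cluster_size), 1L), n - 1L)
    for (kk in if (k_hi >= 2L) seq(k_hi, 2L) else integer()) {
      if (min(table(stats::cutree(hc, kk))) < min_cluster_size) next
      gap <- if (h[n - kk] > 0) h[n - kk + 1L] / h[n - kk]
             else if (h[n - kk + 1L] > 0) Inf else 1
      if (gap >= gap_min) { k <- kk; break }
    }
    labels <- stats::cutree(hc, k)
  } else {
    labels <- stats::cutree(hc, k)
    if (min(table(labels)) < min_cluster_size)
      warning("fixed k violates the minimum cluster size")
  }
  structure(list(labels = labels, linkage = hc,
                 genes_used = rownames(cm$values),
                 min_cluster_size = min_cluster_size, k = k,
                 iterations = list(), converged = NA),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d cells in %d clusters (sizes %s) on %d genes\n",
              length(x$labels), length(unique(x$labels)),
              paste(sort(table(x$labels), decreasing = TRUE), collapse = "/"),
              length(x$genes_used)))
  if (length(x$iterations))
    cat(sprintf("  refinement: %d round(s), converged: %s\n",
                length(x$iterations), x$converged))
  invisible(x)
}

# label-permutation-invariant partition identity
partitions_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  norm <- function(l) match(l, unique(l))
  identical(norm(a), norm(b))
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors over the same cells.
#' @return ARI in \[-1, 1\]; 1 for identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  nt <- comb2(sum(tab))
  expected <- si * sj / nt
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

#' Iterative DE-driven cluster refinement
#'
#' Reproduces the two-step refinement loop of the workflow: cluster on
#' the current gene set, run all pairwise negative-binomial contrasts
#' between the resulting clusters at the standard gates (fold >= 2,
#' FDR <= 0.05, detection at >= 5 CPM in >= 20% of either cluster), set
#' the new gene set to the union of the differentially expressed genes,
#' and repeat until the cell partition no longer changes (compared
#' label-permutation-invariantly) or `max_iter` is reached. Cells on a
#' manual exclusion list are dropped before the first round.
#'
#' @param counts a [count_matrix()] restricted to the analysis cells and
#'   filtered genes.
#' @param e the matching `expression_matrix`.
#' @param initial_genes gene set from HVG selection (reporter already
#'   excluded upstream).
#' @param de_params list of gates: `fold`, `fdr_max`, `detect_cpm`,
#'   `detect_frac` (defaults 2, 0.05, 5, 0.2).
#' @param min_cluster_size minimum cluster size (default 5).
#' @param max_iter refinement cap (default 10).
#' @param exclude cell ids to drop before clustering (manual doublet
#'   annotations); never inferred automatically.
#' @return a `clustering_result` whose `iterations` holds per-round gene
#'   sets and labels, with `converged` set.
#' @export
iterative_refine <- function(counts, e, initial_genes,
                             de_params = list(), min_cluster_size = 5,
                             max_iter = 10, exclude = character()) {
  dp <- utils::modifyList(list(fold = 2, fdr_max = 0.05, detect_cpm = 5,
                               detect_frac = 0.2), de_params)
  if (length(exclude)) {
    keep <- !(cell_ids(counts) %in% exclude)
    counts <- subset_counts(counts, cells = keep)
    e <- subset_expression(e, cells = keep)
  }
  genes <- initial_genes
  iterations <- list()
  res <- NULL; prev_labels <- NULL; converged <- FALSE
  for (it in seq_len(max_iter)) {
    res <- ward_cluster(median_center(e, genes),
                        min_cluster_size = min_cluster_size)
    iterations[[it]] <- list(genes = genes, labels = res$labels)
    if (!is.null(prev_labels) && partitions_equal(res$labels, prev_labels)) {
      converged <- TRUE
      break
    }
    prev_labels <- res$labels
    if (length(unique(res$labels)) < 2) { converged <- TRUE; break }
    new_genes <- pairwise_de_genes(counts, e, res$labels, dp)
    if (!length(new_genes)) {
      warning("differential expression returned no genes; stopping refinement")
      break
    }
    genes <- new_genes
  }
  res$iterations <- iterations
  res$converged <- converged
  res
}

pairwise_de_genes <- function(counts, e, labels, dp) {
  cl <- sort(unique(labels))
  sig <- character()
  for (i in seq_along(cl)) for (j in seq_len(i - 1L)) {
    tab <- nb_contrast(counts, e$size_factors, labels, A = cl[i], B = cl[j],
                       expr = e, fold = dp$fold, fdr_max = dp$fdr_max,
                       detect_cpm = dp$detect_cpm,
                       detect_frac = dp$detect_frac)
    sig <- c(sig, tab$gene_id[tab$significant])
  }
  sort(unique(sig))
}

subset_expression <- function(e, cells) {
  e$values <- e$values[, cells, drop = FALSE]
  e$cpm <- e$cpm[, cells, drop = FALSE]
  e$eff_lib <- e$eff_lib[cells]
  e$size_factors$factor <- e$size_factors$factor[cells]
  e
}
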