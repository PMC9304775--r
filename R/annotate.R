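#' Canonical marker sets for the five MNTB populations
#'
#' The field-standard markers used to identify clusters: neurons by
#' Calb1/Gabra5/Grin2a, astrocytes by Aldh1l1/Slc1a2/Slc1a3,
#' oligodendrocytes by Cnp/Mbp/Sox10, and vascular-associated cells
#' (endothelial cells and pericytes pooled) by Cldn5/Flt1/Pdgfrb.
#'
#' @return named list of gene-id vectors.
#' @export
default_marker_sets <- function() {
  list(Neuron = c("Calb1", "Gabra5", "Grin2a"),
       Astrocyte = c("Aldh1l1", "Slc1a2", "Slc1a3"),
       Oligodendrocyte = c("Cnp", "Mbp", "Sox10"),
       VAC = c("Cldn5", "Flt1", "Pdgfrb"))
}

#' Default ligand-receptor pair table
#'
#' Pathway pairs assembled from the signaling inventories the analysis
#' tracks: FGF (neuronal Fgf9 to astrocytic Fgfr3), VEGF ligands to VAC
#' receptors, TGF-beta ligands to VAC receptor/coreceptor set, and
#' Delta/Jagged ligands to Notch receptors.
#'
#' @return data.frame with columns `ligand`, `receptor`, `pathway`.
#' @export
default_lr_pairs <- function() {
  data.frame(
    ligand = c("Fgf9", "Fgf9", "Vegfa", "Vegfa", "Vegfb", "Tgfb2", "Tgfb2",
               "Tgfb2", "Dll1", "Dll1", "Jag1", "Jag1"),
    receptor = c("Fgfr3", "Fgfr1", "Flt1", "Kdr", "Flt1", "Tgfbr2", "Acvrl1",
                 "Eng", "Notch1", "Notch4", "Notch1", "Notch4"),
    pathway = c("FGF", "FGF", "VEGF", "VEGF", "VEGF", "TGFb", "TGFb", "TGFb",
                "Notch", "Notch", "Notch", "Notch"))
}

#' Marker-based cluster annotation
#'
#' Scores every (cluster, type) combination as the mean, over the type's
#' marker genes, of the cluster's mean log2 CPM minus the gene's grand
#' mean — a marker-enrichment score. Each cluster is assigned the argmax
#' type; ties are flagged ambiguous rather than silently broken. Marker
#' genes absent from the matrix are skipped with a warning; a type whose
#' markers are all absent is reported unassignable.
#'
#' @param e an `expression_matrix`.
#' @param labels cluster labels per cell.
#' @param markers named list of marker gene-id vectors, one per type.
#' @return object of class `cluster_annotation`: `assignment` (cluster ->
#'   type, NA when ambiguous), `scores` (clusters x types), `ambiguous`,
#'   `missing_genes`, `unassignable_types`.
#' @export
assign_cluster_types <- function(e, labels, markers) {
  stopifnot(inherits(e, "expression_matrix"))
  if (!length(markers) || any(!lengths(markers)))
    stop("empty marker set", call. = FALSE)
  if (is.null(names(markers)) || anyDuplicated(names(markers)))
    stop("marker sets must have unique type names", call. = FALSE)
  v <- e$values
  cl <- sort(unique(labels))
  grand <- rowMeans(v)
  missing <- setdiff(unlist(markers), rownames(v))
  if (length(missing))
    warning("marker genes absent and skipped: ",
            paste(missing, collapse = ", "))
  unassignable <- names(markers)[vapply(markers, function(g)
    !any(g %in% rownames(v)), TRUE)]
  scores <- matrix(NA_real_, length(cl), length(markers),
                   dimnames = list(as.character(cl), names(markers)))
  for (k in seq_along(cl)) {
    cells <- labels == cl[k]
    cmean <- rowMeans(v[, cells, drop = FALSE])
    for (t in names(markers)) {
      g <- intersect(markers[[t]], rownames(v))
      if (length(g)) scores[k, t] <- mean(cmean[g] - grand[g])
    }
  }
  assignment <- character(length(cl)); ambiguous <- logical(length(cl))
  for (k in seq_along(cl)) {
    s <- scores[k, ]
    if (all(is.na(s))) { assignment[k] <- NA; next }
    top <- max(s, na.rm = TRUE)
    hits <- names(s)[!is.na(s) & abs(s - top) < 1e-9]
    if (length(hits) > 1) { ambiguous[k] <- TRUE; assignment[k] <- NA }
    else assignment[k] <- hits
  }
  names(assignment) <- as.character(cl); names(ambiguous) <- as.character(cl)
  structure(list(assignment = assignment, scores = scores,
                 ambiguous = ambiguous, missing_genes = missing,
                 unassignable_types = unassignable),
            class = "cluster_annotation")
}

#' @export
print.cluster_annotation <- function(x, ...) {
  for (k in names(x$assignment))
    cat(sprintf("cluster %s -> %s%s\n", k,
                ifelse(is.na(x$assignment[k]), "?", x$assignment[k]),
                ifelse(x$ambiguous[k], " (ambiguous)", "")))
  if (length(x$unassignable_types))
    cat("unassignable types:", paste(x$unassignable_types, collapse = ", "),
        "\n")
  invisible(x)
}

#' Reporter-transcript validation of neuronal clusters
#'
#' One-sided Wilcoxon rank-sum test of the reporter's CPM in each
#' neuron-annotated cluster against all pooled non-neuronal cells, with
#' BH adjustment across the neuron clusters. The clustering input had the
#' reporter removed, so this is an independent check that the clusters
#' labelled neuronal really carry the lineage label. Exact enumeration is
#' used at small sample sizes without ties, the tie-corrected normal
#' approximation otherwise (the stats::wilcox.test conventions).
#'
#' @param e an `expression_matrix` still containing the reporter gene.
#' @param labels cluster labels per cell.
#' @param reporter_gene gene id of the reporter.
#' @param neuron_clusters labels of the clusters annotated neuronal.
#' @param alpha adjusted-p threshold for the pass verdict (default 0.005).
#' @return object of class `reporter_validation`: data.frame `tests`
#'   (cluster, n, p, p_adj), `pass`.
#' @export
reporter_validation <- function(e, labels, reporter_gene, neuron_clusters,
                                alpha = 0.005) {
  stopifnot(inherits(e, "expression_matrix"))
  if (!reporter_gene %in% rownames(e$cpm))
    stop("reporter gene absent: ", reporter_gene, call. = FALSE)
  x <- e$cpm[reporter_gene, ]
  non <- !(labels %in% neuron_clusters)
  if (!any(non)) stop("no non-neuronal cells", call. = FALSE)
  p <- vapply(neuron_clusters, function(k) {
    suppressWarnings(stats::wilcox.test(x[labels == k], x[non],
                                        alternative = "greater")$p.value)
  }, numeric(1))
  tests <- data.frame(cluster = as.character(neuron_clusters),
                      n = vapply(neuron_clusters,
                                 function(k) sum(labels == k), integer(1)),
                      p = p, p_adj = stats::p.adjust(p, "BH"))
  structure(list(tests = tests, alpha = alpha,
                 pass = all(tests$p_adj <= alpha)),
            class = "reporter_validation")
}

#' @export
print.reporter_validation <- function(x, ...) {
  print(x$tests)
  cat(sprintf("pass (all adjusted p <= %g): %s\n", x$alpha, x$pass))
  invisible(x)
}

#' Directional ligand-receptor edges between clusters
#'
#' Formalizes the descriptive sender-to-receiver reading of cluster
#' expression patterns: an edge S -> R is emitted for a pair iff the
#' ligand passes the enrichment rule in the sender's one-vs-rest table
#' and the receptor passes it in the receiver's. The default rule is the
#' DE gate (fold >= 2 up, FDR <= 0.05, detection in the cluster); in
#' `"expressed"` mode mere within-cluster detection (>= 5 CPM in >= 20%
#' of cells by default) suffices. Outputs are descriptive summaries of
#' enrichment patterns, not significance statements about signaling.
#'
#' @param de_tables a `de_table_set` of one-vs-rest contrasts (one per
#'   cluster).
#' @param lr data.frame with columns `ligand`, `receptor`, `pathway`.
#' @param mode `"enriched"` (default) or `"expressed"`.
#' @param fold,fdr_max,detect_frac rule parameters.
#' @return object of class `lr_edges`: `edges` data.frame ordered by
#'   (pathway, sender, receiver) with the evidence values, and
#'   `unresolved` (pair rows whose genes are absent, flagged not silently
#'   dropped).
#' @export
ligand_receptor_directionality <- function(de_tables, lr,
                                           mode = c("enriched", "expressed"),
                                           fold = 2, fdr_max = 0.05,
                                           detect_frac = 0.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(de_tables, "de_table_set"))
  groups <- names(de_tables)
  gene_universe <- de_tables[[1]]$gene_id
  unresolved <- lr[!(lr$ligand %in% gene_universe) |
                     !(lr$receptor %in% gene_universe), , drop = FALSE]
  lr_ok <- lr[lr$ligand %in% gene_universe & lr$receptor %in% gene_universe, ,
              drop = FALSE]
  passes <- function(tab, gene) {
    row <- tab[tab$gene_id == gene, ]
    if (mode == "enriched")
      row$fold_change >= fold & row$fdr <= fdr_max &
        row$detect_frac_A >= detect_frac
    else
      row$detect_frac_A >= detect_frac
  }
  evidence <- function(tab, gene) tab[tab$gene_id == gene,
                                      c("fold_change", "fdr",
                                        "detect_frac_A")]
  rows <- list()
  for (i in seq_len(nrow(lr_ok))) {
    lig <- lr_ok$ligand[i]; rec <- lr_ok$receptor[i]
    for (s in groups) for (r in groups) {
      if (passes(de_tables[[s]], lig) && passes(de_tables[[r]], rec)) {
        es <- evidence(de_tables[[s]], lig)
        er <- evidence(de_tables[[r]], rec)
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = lr_ok$pathway[i], sender = s, receiver = r,
          ligand = lig, receptor = rec,
          ligand_fold = es$fold_change, ligand_fdr = es$fdr,
          ligand_detect = es$detect_frac_A,
          receptor_fold = er$fold_change, receptor_fdr = er$fdr,
          receptor_detect = er$detect_frac_A)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows)
           else data.frame(pathway = character(), sender = character(),
                           receiver = character(), ligand = character(),
                           receptor = character())
  edges <- edges[order(edges$pathway, edges$sender, edges$receiver), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, unresolved = unresolved, mode = mode),
            class = "lr_edges")
}

#' @export
print.lr_edges <- function(x, ...) {
  cat(sprintf("lr_edges (%s mode): %d edges\n", x$mode, nrow(x$edges)))
  if (nrow(x$edges))
    print(x$edges[, c("pathway", "sender", "receiver", "ligand", "receptor")])
  if (nrow(x$unresolved))
    cat("unresolved pairs:", nrow(x$unresolved), "\n")
  invisible(x)
}
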