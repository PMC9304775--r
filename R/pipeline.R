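#' Pipeline configuration with the workflow's default thresholds
#'
#' Every scalar default equals the workflow's stated value: 3 MADs for
#' cell QC; 10 counts in 3 cells for gene filtering (fourth-quartile
#' restriction optional); twofold variance deviation at FDR < 0.05 for
#' HVGs; Spearman |rho| > 0.4 at FDR <= 0.001; minimum cluster size 5;
#' DE at >= 2-fold, FDR <= 0.05 with the 5 CPM / 20% detection gate;
#' reporter validation at adjusted p <= 0.005; BKY q = 0.01.
#'
#' @param ... overrides of the listed fields.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(n_mads = 3, min_count = 10, min_cells = 3,
              quartile_filter = FALSE,
              pool_sizes = c(20, 40, 60, 80, 100), min_mean = 1,
              pseudocount = 1,
              loess_span = 0.3, var_fold = 2, var_fdr = 0.05,
              rho_min = 0.4, corr_fdr = 0.001, n_perm = 10000,
              min_cluster_size = 5, max_iter = 10,
              de_fold = 2, de_fdr = 0.05, detect_cpm = 5, detect_frac = 0.2,
              reporter_alpha = 0.005, bky_q = 0.01,
              exclude_cells = character(), seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  structure(utils::modifyList(cfg, over), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm,
                                   paste(format(x[[nm]]), collapse = ",")))
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' QC -> gene filtering -> deconvolution normalization -> HVG selection
#' (reporter removed first) -> Spearman correlation filter -> iterative
#' DE-driven Ward clustering -> marker annotation -> merged one-vs-rest
#' DE -> reporter validation -> ligand-receptor edges. Intermediates are
#' persisted as TSV when `out_dir` is given; stage boundaries are logged
#' with tallies via `message()`.
#'
#' @param m a [count_matrix()] or `synthetic_dataset`.
#' @param config a [pipeline_config()].
#' @param markers marker sets for annotation ([default_marker_sets()]).
#' @param lr_pairs ligand-receptor table ([default_lr_pairs()]).
#' @param out_dir optional directory for TSV intermediates.
#' @return object of class `run_report`.
#' @export
run_pipeline <- function(m, config = pipeline_config(),
                         markers = default_marker_sets(),
                         lr_pairs = default_lr_pairs(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (inherits(m, "synthetic_dataset")) {
    truth <- data.frame(cell_id = cell_ids(m$counts),
                        true_type = m$true_type,
                        is_doublet = m$is_doublet,
                        is_low_quality = m$is_low_quality)
    m <- m$counts
  }
  stopifnot(inherits(m, "count_matrix"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  persist <- function(obj, name) {
    if (!is.null(out_dir))
      utils::write.table(obj, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage <- function(...) message("[scmntb] ", sprintf(...))
  report <- list(config = config, tallies = list())

  # --- cell QC ------------------------------------------------------------
  qc <- compute_cell_qc(m)
  keep_cells <- mad_outlier_filter(qc, n_mads = config$n_mads)
  keep_cells[cell_ids(m) %in% config$exclude_cells] <- FALSE
  stage("QC: kept %d / %d cells", sum(keep_cells), length(keep_cells))
  persist(cbind(qc, keep = keep_cells), "cell_qc")
  report$tallies$cells_in <- length(keep_cells)
  report$tallies$cells_kept <- sum(keep_cells)
  m1 <- subset_counts(m, cells = keep_cells)
  if (!is.null(truth)) truth <- truth[keep_cells, , drop = FALSE]

  # --- gene filtering -----------------------------------------------------
  keep_genes <- filter_genes(m1, min_count = config$min_count,
                             min_cells = config$min_cells,
                             quartile_filter = config$quartile_filter)
  keep_genes <- keep_genes | m1$gene_flags$reporter  # keep for validation
  stage("gene filter: kept %d / %d genes", sum(keep_genes),
        length(keep_genes))
  report$tallies$genes_in <- length(keep_genes)
  report$tallies$genes_kept <- sum(keep_genes)
  m2 <- subset_counts(m1, genes = keep_genes)

  # --- normalization ------------------------------------------------------
  sf <- deconvolution_size_factors(m2, pool_sizes = config$pool_sizes,
                                   min_mean = config$min_mean)
  e <- log2_cpm(m2, sf, pseudocount = config$pseudocount)
  stage("normalization: size factors in [%.2f, %.2f]", min(sf$factor),
        max(sf$factor))
  persist(data.frame(cell_id = cell_ids(m2), size_factor = sf$factor),
          "size_factors")

  # --- HVG selection (reporter excluded from the feature space) -----------
  reporter_id <- gene_ids(m2)[m2$gene_flags$reporter]
  non_reporter <- setdiff(gene_ids(m2), reporter_id)
  e_feat <- e
  e_feat$values <- e$values[non_reporter, , drop = FALSE]
  e_feat$cpm <- e$cpm[non_reporter, , drop = FALSE]
  vfit <- fit_variance_trend(e_feat, span = config$loess_span)
  hvg <- select_variable_genes(vfit, fold = config$var_fold,
                               fdr_max = config$var_fdr)
  stage("HVG: %d variable genes", length(hvg))
  persist(vfit, "variance_fit")
  corr <- correlation_filter(e_feat, hvg, rho_min = config$rho_min,
                             fdr_max = config$corr_fdr,
                             n_perm = config$n_perm, seed = config$seed)
  stage("correlation filter: %d -> %d genes", length(hvg),
        length(corr$kept_genes))
  report$tallies$hvg <- length(hvg)
  report$tallies$hvg_correlated <- length(corr$kept_genes)
  if (length(corr$kept_genes) < 2)
    stop("stage correlation_filter: fewer than 2 genes survive",
         call. = FALSE)

  # --- iterative clustering (counts without the reporter) -----------------
  m_feat <- subset_counts(m2, genes = !m2$gene_flags$reporter)
  clus <- iterative_refine(m_feat, e_feat, corr$kept_genes,
                           de_params = list(fold = config$de_fold,
                                            fdr_max = config$de_fdr,
                                            detect_cpm = config$detect_cpm,
                                            detect_frac = config$detect_frac),
                           min_cluster_size = config$min_cluster_size,
                           max_iter = config$max_iter)
  stage("clustering: %d clusters after %d round(s), converged: %s",
        length(unique(clus$labels)), length(clus$iterations),
        clus$converged)
  persist(data.frame(cell_id = cell_ids(m_feat), cluster = clus$labels),
          "clusters")
  report$tallies$cluster_sizes <- as.integer(table(clus$labels))
  report$tallies$refine_rounds <- length(clus$iterations)

  # --- annotation ---------------------------------------------------------
  ann <- assign_cluster_types(e_feat, clus$labels, markers)
  stage("annotation: %s",
        paste(sprintf("%s=%s", names(ann$assignment), ann$assignment),
              collapse = ", "))

  # --- merged one-vs-rest DE ----------------------------------------------
  merge_map <- ann$assignment
  merge_map[is.na(merge_map)] <- paste0("cluster", names(merge_map)[
    is.na(merge_map)])
  de <- neuron_combined_one_vs_rest(m_feat, sf, clus$labels,
                                    merge_map = merge_map, expr = e_feat,
                                    fold = config$de_fold,
                                    fdr_max = config$de_fdr,
                                    detect_cpm = config$detect_cpm,
                                    detect_frac = config$detect_frac)
  for (g in names(de)) persist(de[[g]], paste0("de_", g, "_vs_rest"))
  stage("DE: %s", paste(sprintf("%s: %d", names(de),
                                vapply(de, function(t) sum(t$significant),
                                       integer(1))), collapse = ", "))

  # --- reporter validation ------------------------------------------------
  rep_val <- NULL
  neuron_clusters <- names(ann$assignment)[!is.na(ann$assignment) &
                                             ann$assignment == "Neuron"]
  if (length(reporter_id) && length(neuron_clusters)) {
    rep_val <- reporter_validation(e, clus$labels, reporter_id,
                                   neuron_clusters,
                                   alpha = config$reporter_alpha)
    stage("reporter validation: %s (max adjusted p %.2g)",
          ifelse(rep_val$pass, "pass", "FAIL"), max(rep_val$tests$p_adj))
  }

  # --- ligand-receptor edges ----------------------------------------------
  edges <- ligand_receptor_directionality(de, lr_pairs,
                                          fold = config$de_fold,
                                          fdr_max = config$de_fdr,
                                          detect_frac = config$detect_frac)
  stage("signaling: %d directed edges", nrow(edges$edges))
  persist(edges$edges, "lr_edges")

  ari <- NA_real_
  if (!is.null(truth))
    ari <- adjusted_rand(clus$labels, truth$true_type)

  report <- c(report, list(qc = qc, keep_cells = keep_cells,
                           keep_genes = keep_genes, size_factors = sf,
                           expression = e, variance_fit = vfit,
                           correlation = corr, clustering = clus,
                           annotation = ann, de = de,
                           reporter_validation = rep_val, edges = edges,
                           truth = truth, ari = ari))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  t <- x$tallies
  cat("run_report\n")
  cat(sprintf("  cells: %d -> %d; genes: %d -> %d\n", t$cells_in,
              t$cells_kept, t$genes_in, t$genes_kept))
  cat(sprintf("  HVGs: %d (-> %d after correlation filter)\n", t$hvg,
              t$hvg_correlated))
  cat(sprintf("  clusters: %s (after %d refinement round(s), converged %s)\n",
              paste(t$cluster_sizes, collapse = "/"), t$refine_rounds,
              x$clustering$converged))
  cat("  annotation:",
      paste(sprintf("%s=%s", names(x$annotation$assignment),
                    x$annotation$assignment), collapse = ", "), "\n")
  if (!is.null(x$reporter_validation))
    cat(sprintf("  reporter validation: %s\n",
                ifelse(x$reporter_validation$pass, "pass", "FAIL")))
  if (!is.na(x$ari)) cat(sprintf("  ARI vs ground truth: %.3f\n", x$ari))
  cat(sprintf("  ligand-receptor edges: %d\n", nrow(x$edges$edges)))
  invisible(x)
}
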