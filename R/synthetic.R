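#' Cell-type expression profile for simulation
#'
#' @param name type label.
#' @param n_cells number of cells of this type.
#' @param mean_expression nonnegative per-gene rate vector (expected
#'   transcript share when the library-size multiplier is 1).
#' @param marker_genes gene ids (or indices) whose rate is multiplied by
#'   `marker_fold` in this type.
#' @param marker_fold multiplicative marker enrichment, >= 1.
#' @param neuron logical; neuron-flagged profiles express the reporter.
#' @export
cell_type_profile <- function(name, n_cells, mean_expression,
                              marker_genes = character(), marker_fold = 1,
                              neuron = FALSE) {
  if (any(mean_expression < 0)) stop("negative rates", call. = FALSE)
  if (marker_fold < 1) stop("marker_fold must be >= 1", call. = FALSE)
  if (n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  structure(list(name = name, n_cells = n_cells,
                 mean_expression = mean_expression,
                 marker_genes = marker_genes, marker_fold = marker_fold,
                 neuron = neuron),
            class = "cell_type_profile")
}

#' Simulation configuration
#'
#' Bundles everything [generate_dataset()] needs. Counts are drawn from a
#' negative binomial with variance mu + alpha * mu^2; `nb_dispersion` is
#' alpha (0 gives Poisson). Per-cell library-size multipliers are
#' log-normal. The reporter transcript is restricted to neuron-flagged
#' profiles apart from an optional leakage rate.
#'
#' @param profiles list of [cell_type_profile()] (>= 2 for a clustering
#'   test surface; 1 is allowed for limiting-case checks).
#' @param n_genes,n_mito_genes gene universe size and number of
#'   mitochondrial genes (`n_mito_genes < n_genes`).
#' @param reporter_gene gene id of the reporter transcript.
#' @param library_size_lognormal `c(meanlog, sdlog)` of the per-cell
#'   library-size multiplier.
#' @param nb_dispersion scalar or per-gene alpha >= 0.
#' @param frac_low_quality,frac_doublets artifact proportions in `[0, 1]`,
#'   applied by [inject_artifacts()].
#' @param reporter_leakage relative reporter rate in non-neuron profiles
#'   (default 0).
#' @param seed integer fixing all randomness.
#' @export
simulation_config <- function(profiles, n_genes, n_mito_genes = 0,
                              reporter_gene = "tdTomato",
                              library_size_lognormal = c(log(5e4), 0.3),
                              nb_dispersion = 0.1,
                              frac_low_quality = 0, frac_doublets = 0,
                              reporter_leakage = 0, seed = 1L) {
  if (length(profiles) == 0) stop("empty profiles", call. = FALSE)
  if (!all(vapply(profiles, inherits, TRUE, "cell_type_profile")))
    stop("profiles must be cell_type_profile objects", call. = FALSE)
  if (n_mito_genes >= n_genes) stop("n_mito_genes must be < n_genes", call. = FALSE)
  if (frac_low_quality < 0 || frac_low_quality > 1 ||
      frac_doublets < 0 || frac_doublets > 1)
    stop("artifact fractions must be in [0, 1]", call. = FALSE)
  if (any(nb_dispersion < 0)) stop("nb_dispersion must be >= 0", call. = FALSE)
  for (p in profiles)
    if (length(p$mean_expression) != n_genes)
      stop("profile '", p$name, "' rate vector length != n_genes", call. = FALSE)
  structure(list(profiles = profiles, n_genes = n_genes,
                 n_mito_genes = n_mito_genes, reporter_gene = reporter_gene,
                 library_size_lognormal = library_size_lognormal,
                 nb_dispersion = nb_dispersion,
                 frac_low_quality = frac_low_quality,
                 frac_doublets = frac_doublets,
                 reporter_leakage = reporter_leakage,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default study-like simulation configuration
#'
#' Emulates the dissociated early-postnatal MNTB sample the pipeline was
#' designed around: five populations (two neuronal clusters N1/N2,
#' astrocytes, oligodendrocytes, vascular-associated cells), 240 cells in
#' total, strongly type-enriched marker genes (8-fold by default) that use
#' the field's marker symbols (Calb1/Gabra5/Grin2a, Aldh1l1/Slc1a2/Slc1a3,
#' Cnp/Mbp/Sox10, Cldn5/Flt1/Pdgfrb), a highly expressed tdTomato reporter
#' restricted to neurons, ligand/receptor genes planted with the expected
#' enrichment (Fgf9 in neurons, Fgfr3 in astrocytes, VEGF/TGFb receptors
#' in VACs, Notch components in glia/VACs), mitochondrial genes at ~3% of
#' baseline counts, and log-normal per-cell depth.
#'
#' @param n_genes size of the gene universe (markers and named genes are
#'   carved out of it).
#' @param n_cells per-type cell numbers, named.
#' @param marker_fold marker enrichment factor.
#' @param n_markers_per_type planted type-specific markers per type
#'   (named ones included).
#' @param nb_dispersion,library_size_lognormal,frac_low_quality,frac_doublets,reporter_leakage,seed
#'   passed through to [simulation_config()].
#' @return a [simulation_config()] whose profiles carry a `marker_map`
#'   attribute (type -> marker gene ids, plus a pan-neuronal "Neuron" set).
#' @export
default_simulation_config <- function(n_genes = 2000,
                                      n_cells = c(N1 = 60, N2 = 50,
                                                  Astrocyte = 50,
                                                  Oligodendrocyte = 40,
                                                  VAC = 40),
                                      marker_fold = 8,
                                      n_markers_per_type = 20,
                                      nb_dispersion = 0.1,
                                      library_size_lognormal = c(log(5e4), 0.3),
                                      frac_low_quality = 0,
                                      frac_doublets = 0,
                                      reporter_leakage = 0,
                                      seed = 1L) {
  set.seed(seed)
  n_mito <- 10L
  named <- list(
    Neuron = c("Calb1", "Gabra5", "Grin2a", "Fgf9", "Snap25", "Syp",
               "Nefl", "Gap43", "Stmn2", "Tubb3"),
    Astrocyte = c("Aldh1l1", "Slc1a2", "Slc1a3", "Fgfr3", "Aqp4", "Gfap",
                  "Tnc", "Agt", "Slc6a11", "Notch1"),
    Oligodendrocyte = c("Cnp", "Mbp", "Sox10", "Plp1", "Olig2", "Ugt8a",
                        "Tnr", "Bcas1", "Sox6", "Dll1"),
    VAC = c("Cldn5", "Flt1", "Pdgfrb", "Acvrl1", "Tgfbr2", "Eng", "Kdr",
            "Icam2", "Tek", "Jag1"))
  broad <- c("Vegfa", "Vegfb", "Tgfb2", "Actb", "Gapdh")
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  gene_ids[seq_len(n_mito)] <- sprintf("mt-%d", seq_len(n_mito))
  gene_ids[n_mito + 1L] <- "tdTomato"
  slot <- n_mito + 1L
  place <- function(ids, names_to_place) {
    for (nm in names_to_place) { slot <<- slot + 1L; ids[slot] <- nm }
    ids
  }
  gene_ids <- place(gene_ids, unlist(named, use.names = FALSE))
  gene_ids <- place(gene_ids, broad)

  n_extra <- max(0L, n_markers_per_type - 10L)
  extra <- lapply(names(n_cells), function(ty) {
    ids <- sprintf("mk%s_%02d", ty, seq_len(n_extra))
    gene_ids <<- place(gene_ids, ids)
    ids
  })
  names(extra) <- names(n_cells)

  marker_map <- list(
    Neuron = named$Neuron,
    N1 = extra$N1,
    N2 = extra$N2,
    Astrocyte = c(named$Astrocyte, extra$Astrocyte),
    Oligodendrocyte = c(named$Oligodendrocyte, extra$Oligodendrocyte),
    VAC = c(named$VAC, extra$VAC))

  # baseline relative rates: heavy-tailed, normalized to sum 1; mito
  # genes set to ~3% of transcripts, reporter ~0.5% in neurons
  base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.2)
  base[seq_len(n_mito)] <- 0
  base[gene_ids == "tdTomato"] <- 0
  base <- base / sum(base) * 0.965
  base[seq_len(n_mito)] <- 0.03 / n_mito
  housekeep <- gene_ids %in% broad
  base[housekeep] <- pmax(base[housekeep], stats::quantile(base[base > 0], 0.9))
  reporter_rate <- 0.005

  mk_profile <- function(ty) {
    rate <- base
    neuron <- ty %in% c("N1", "N2")
    # non-neuron profiles carry the same nominal rate; generate_dataset
    # scales it by the configured leakage (0 by default)
    rate[gene_ids == "tdTomato"] <- reporter_rate
    markers <- if (neuron) c(marker_map$Neuron, marker_map[[ty]])
               else marker_map[[ty]]
    cell_type_profile(ty, n_cells[[ty]], rate, marker_genes = markers,
                      marker_fold = marker_fold, neuron = neuron)
  }
  profiles <- lapply(names(n_cells), mk_profile)

  cfg <- simulation_config(profiles, n_genes = n_genes, n_mito_genes = n_mito,
                           reporter_gene = "tdTomato",
                           library_size_lognormal = library_size_lognormal,
                           nb_dispersion = nb_dispersion,
                           frac_low_quality = frac_low_quality,
                           frac_doublets = frac_doublets,
                           reporter_leakage = reporter_leakage, seed = seed)
  attr(cfg, "gene_ids") <- gene_ids
  attr(cfg, "marker_map") <- marker_map
  cfg
}

#' Generate a synthetic single-cell count dataset
#'
#' Draws counts `counts[g, c] ~ NB(mean = L_c * rate_g, dispersion alpha)`
#' where `L_c` is a log-normal per-cell library-size multiplier and
#' `rate_g` is the cell's type profile with markers boosted by
#' `marker_fold`. The reporter transcript is nonzero only in neuron
#' profiles (up to the configured leakage). Low-quality cells and doublets
#' are then injected per the config fractions. Deterministic under the
#' config seed.
#'
#' @param config a [simulation_config()].
#' @return an object of class `synthetic_dataset`: `counts`
#'   ([count_matrix()]), `true_type`, `is_doublet`, `is_low_quality`,
#'   `marker_map`, `library_size` (true multipliers), `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_genes <- config$n_genes
  ids <- attr(config, "gene_ids")
  if (is.null(ids)) {
    ids <- sprintf("gene%04d", seq_len(n_genes))
    if (config$n_mito_genes > 0)
      ids[seq_len(config$n_mito_genes)] <- sprintf("mt-%d",
                                                   seq_len(config$n_mito_genes))
    if (!config$reporter_gene %in% ids && config$n_mito_genes + 1L <= n_genes)
      ids[config$n_mito_genes + 1L] <- config$reporter_gene
  }
  rep_idx <- match(config$reporter_gene, ids)
  alpha <- rep_len(config$nb_dispersion, n_genes)

  cols <- list(); types <- character(); libs <- numeric()
  for (p in config$profiles) {
    if (p$n_cells == 0) next
    rate <- p$mean_expression
    midx <- if (is.character(p$marker_genes)) match(p$marker_genes, ids)
            else p$marker_genes
    if (anyNA(midx)) stop("marker gene not in gene universe", call. = FALSE)
    rate[midx] <- rate[midx] * p$marker_fold
    if (!is.na(rep_idx) && !p$neuron)
      rate[rep_idx] <- rate[rep_idx] * config$reporter_leakage
    L <- stats::rlnorm(p$n_cells, config$library_size_lognormal[1],
                       config$library_size_lognormal[2])
    mu <- outer(rate, L)                        # genes x cells
    x <- draw_nb(mu, alpha)
    cols <- c(cols, list(x))
    types <- c(types, rep(p$name, p$n_cells))
    libs <- c(libs, L)
  }
  counts <- if (length(cols)) do.call(cbind, cols)
            else matrix(0, n_genes, 0)
  cell_id <- sprintf("cell%04d", seq_len(ncol(counts)))
  cm <- count_matrix(counts, gene_ids = ids, cell_ids = cell_id,
                     mito = c(rep(TRUE, config$n_mito_genes),
                              rep(FALSE, n_genes - config$n_mito_genes)),
                     reporter = config$reporter_gene)
  ds <- structure(list(counts = cm, true_type = types,
                       is_doublet = rep(FALSE, length(types)),
                       is_low_quality = rep(FALSE, length(types)),
                       marker_map = attr(config, "marker_map"),
                       library_size = libs, config = config),
                  class = "synthetic_dataset")
  if (config$frac_low_quality > 0 || config$frac_doublets > 0)
    ds <- inject_artifacts(ds, config$frac_low_quality, config$frac_doublets,
                           seed = config$seed + 1L)
  ds
}

draw_nb <- function(mu, alpha) {
  out <- matrix(0, nrow(mu), ncol(mu))
  pois <- alpha < 1e-12
  n <- ncol(mu)
  if (any(pois))
    out[pois, ] <- stats::rpois(sum(pois) * n, as.vector(mu[pois, , drop = FALSE]))
  if (any(!pois)) {
    a <- alpha[!pois]
    out[!pois, ] <- stats::rnbinom(sum(!pois) * n,
                                   size = rep(1 / a, n),
                                   mu = as.vector(mu[!pois, , drop = FALSE]))
  }
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genes x %d cells; types: %s\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              paste(sprintf("%s=%d", names(table(x$true_type)),
                            table(x$true_type)), collapse = ", ")))
  cat(sprintf("  low-quality: %d, doublets: %d\n",
              sum(x$is_low_quality), sum(x$is_doublet)))
  invisible(x)
}

#' Inject low-quality cells and doublets
#'
#' Low-quality cells are existing cells whose counts are binomially
#' downsampled to `thin_frac` of their original total and whose
#' mitochondrial share is then inflated to at least `mito_target` by a
#' multinomial redraw that preserves the downsampled total. Doublets are
#' exact element-wise sums of two randomly paired cells, appended as new
#' columns; their `true_type` records both parents ("A+B").
#'
#' @param ds a `synthetic_dataset`.
#' @param frac_low_quality,frac_doublets proportions in `[0, 1]` of the
#'   current cell count.
#' @param seed integer.
#' @param thin_frac downsampling target (< 0.25 per the QC design point).
#' @param mito_target minimum mitochondrial fraction of low-quality cells.
#' @return the modified `synthetic_dataset` with flags updated.
#' @export
inject_artifacts <- function(ds, frac_low_quality = 0, frac_doublets = 0,
                             seed = 1L, thin_frac = 0.2, mito_target = 0.5) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (frac_low_quality < 0 || frac_low_quality > 1 ||
      frac_doublets < 0 || frac_doublets > 1)
    stop("fractions must be in [0, 1]", call. = FALSE)
  if (frac_low_quality == 0 && frac_doublets == 0) return(ds)
  set.seed(seed)
  counts <- as.matrix(ds$counts$counts)
  mito <- ds$counts$gene_flags$mito
  n <- ncol(counts)

  n_lq <- round(frac_low_quality * n)
  if (n_lq > 0) {
    lq <- sample(which(!ds$is_doublet & !ds$is_low_quality), n_lq)
    for (c0 in lq) {
      v <- counts[, c0]
      v <- stats::rbinom(length(v), v, thin_frac)   # thin library
      tot <- sum(v)
      if (tot > 0) {
        m_tot <- ceiling(mito_target * tot)
        pm <- v[mito] + 0.5
        vm <- stats::rmultinom(1, m_tot, pm)[, 1]
        pn <- v[!mito]
        vn <- if (tot - m_tot > 0 && sum(pn) > 0)
                stats::rmultinom(1, tot - m_tot, pn)[, 1]
              else rep(0L, sum(!mito))
        v[mito] <- vm; v[!mito] <- vn
      }
      counts[, c0] <- v
    }
    ds$is_low_quality[lq] <- TRUE
  }

  n_db <- round(frac_doublets * n)
  if (n_db > 0) {
    eligible <- which(!ds$is_doublet & !ds$is_low_quality)
    pick <- sample(eligible, 2L * n_db)
    a <- pick[seq_len(n_db)]; b <- pick[n_db + seq_len(n_db)]
    dbl <- counts[, a, drop = FALSE] + counts[, b, drop = FALSE]
    colnames(dbl) <- sprintf("doublet%03d", seq_len(n_db))
    counts <- cbind(counts, dbl)
    ds$true_type <- c(ds$true_type,
                      paste(ds$true_type[a], ds$true_type[b], sep = "+"))
    ds$is_doublet <- c(ds$is_doublet, rep(TRUE, n_db))
    ds$is_low_quality <- c(ds$is_low_quality, rep(FALSE, n_db))
    ds$library_size <- c(ds$library_size,
                         ds$library_size[a] + ds$library_size[b])
    attr(ds, "doublet_parents") <- cbind(a, b)
  }

  ds$counts <- count_matrix(counts,
                            mito = mito,
                            reporter = ds$counts$gene_flags$reporter,
                            cell_meta = NULL)
  ds
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits Matrix Market sparse counts (`matrix.mtx`, 1-based coordinate
#' format), `genes.tsv` (id, mito, reporter), `cells.tsv` (id, true_type,
#' is_doublet, is_low_quality, excluded_manually) and `truth.tsv`
#' (cell_type, gene_id marker map). Round-trips losslessly through
#' [read_dataset()].
#'
#' @param ds a `synthetic_dataset`.
#' @param directory output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(ds, directory) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create ", directory, call. = FALSE)
  Matrix::writeMM(ds$counts$counts, file.path(directory, "matrix.mtx"))
  gf <- data.frame(gene_id = gene_ids(ds$counts),
                   mito = ds$counts$gene_flags$mito,
                   reporter = ds$counts$gene_flags$reporter)
  utils::write.table(gf, file.path(directory, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cf <- data.frame(cell_id = cell_ids(ds$counts),
                   true_type = ds$true_type,
                   is_doublet = ds$is_doublet,
                   is_low_quality = ds$is_low_quality,
                   excluded_manually = ds$counts$cell_meta$excluded_manually)
  utils::write.table(cf, file.path(directory, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mm <- ds$marker_map
  tf <- if (length(mm))
          data.frame(cell_type = rep(names(mm), lengths(mm)),
                     gene_id = unlist(mm, use.names = FALSE))
        else data.frame(cell_type = character(), gene_id = character())
  utils::write.table(tf, file.path(directory, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(directory)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory directory containing `matrix.mtx` and TSV sidecars.
#' @return a `synthetic_dataset`.
#' @export
read_dataset <- function(directory) {
  cm <- read_counts(file.path(directory, "matrix.mtx"),
                    genes = file.path(directory, "genes.tsv"),
                    cells = file.path(directory, "cells.tsv"))
  cf <- utils::read.delim(file.path(directory, "cells.tsv"))
  tfp <- file.path(directory, "truth.tsv")
  mm <- list()
  if (file.exists(tfp)) {
    tf <- utils::read.delim(tfp)
    if (nrow(tf)) mm <- split(tf$gene_id, tf$cell_type)
  }
  structure(list(counts = cm,
                 true_type = if (nrow(cf)) as.character(cf$true_type) else character(),
                 is_doublet = if (nrow(cf)) cf$is_doublet else logical(),
                 is_low_quality = if (nrow(cf)) cf$is_low_quality else logical(),
                 marker_map = mm, library_size = NULL, config = NULL),
            class = "synthetic_dataset")
}
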