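#' Sparse gene-by-cell count container
#'
#' The root object of the pipeline: a sparse integer matrix of molecule
#' counts (genes in rows, cells in columns) plus per-gene flags marking
#' mitochondrial genes and the neuronal reporter transcript, and per-cell
#' metadata (batch label and any manual exclusion from capture-site
#' inspection, e.g. doublet captures spotted on the imaging station).
#'
#' @param counts matrix or sparse Matrix of nonnegative integer counts,
#'   genes x cells.
#' @param gene_ids,cell_ids character vectors of unique identifiers;
#'   default to dimnames.
#' @param mito logical vector flagging mitochondrial genes, or character
#'   vector of gene ids. Defaults to ids starting with `"mt-"` (case
#'   insensitive).
#' @param reporter logical or character flagging the reporter transcript
#'   (e.g. tdTomato in an En1-Cre;Ai9 cross). Defaults to the id
#'   `"tdTomato"`.
#' @param cell_meta data.frame with optional columns `batch` and
#'   `excluded_manually`, one row per cell.
#' @return An object of class `count_matrix` with elements `counts`
#'   (dgCMatrix), `gene_flags` (data.frame: mito, reporter) and
#'   `cell_meta` (data.frame: batch, excluded_manually).
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         cell_ids = colnames(counts),
                         mito = NULL, reporter = NULL, cell_meta = NULL) {
  counts <- as_dgc(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%04d", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length does not match number of rows", call. = FALSE)
  if (length(cell_ids) != ncol(counts))
    stop("cell_ids length does not match number of columns", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)])[1:3],
                                       collapse = ", "), call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ", paste(unique(cell_ids[duplicated(cell_ids)])[1:3],
                                       collapse = ", "), call. = FALSE)
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be nonnegative integers", call. = FALSE)
  dimnames(counts) <- list(gene_ids, cell_ids)

  mito <- resolve_flag(mito, gene_ids,
                       default = grepl("^mt-", gene_ids, ignore.case = TRUE))
  reporter <- resolve_flag(reporter, gene_ids, default = gene_ids == "tdTomato")
  gene_flags <- data.frame(mito = mito, reporter = reporter,
                           row.names = gene_ids)

  cm <- data.frame(batch = rep("batch1", length(cell_ids)),
                   excluded_manually = rep(FALSE, length(cell_ids)),
                   row.names = cell_ids, stringsAsFactors = FALSE)
  if (!is.null(cell_meta)) {
    if (nrow(cell_meta) != length(cell_ids))
      stop("cell_meta must have one row per cell", call. = FALSE)
    for (col in intersect(names(cell_meta), c("batch", "excluded_manually")))
      cm[[col]] <- cell_meta[[col]]
  }

  structure(list(counts = counts, gene_flags = gene_flags, cell_meta = cm),
            class = "count_matrix")
}

as_dgc <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  m
}

resolve_flag <- function(flag, ids, default) {
  if (is.null(flag)) return(default)
  if (is.character(flag)) return(ids %in% flag)
  if (is.logical(flag) && length(flag) == length(ids)) return(flag)
  stop("flag must be NULL, a character vector of ids, or a logical per gene",
       call. = FALSE)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%d mito, %s reporter)\n",
              nrow(x$counts), ncol(x$counts), sum(x$gene_flags$mito),
              if (any(x$gene_flags$reporter))
                rownames(x$gene_flags)[x$gene_flags$reporter][1] else "no"))
  invisible(x)
}

gene_ids <- function(m) rownames(m$counts)
cell_ids <- function(m) colnames(m$counts)

#' Subset a count matrix
#'
#' @param m a [count_matrix()].
#' @param genes,cells logical, integer or character index over genes/cells
#'   (NULL keeps all).
#' @return a `count_matrix` restricted to the selection.
#' @export
subset_counts <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  gi <- if (is.null(genes)) seq_len(nrow(m$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(m$counts)) else cells
  cnt <- m$counts[gi, ci, drop = FALSE]
  count_matrix(cnt,
               mito = m$gene_flags$mito[match(rownames(cnt), gene_ids(m))],
               reporter = m$gene_flags$reporter[match(rownames(cnt), gene_ids(m))],
               cell_meta = m$cell_meta[match(colnames(cnt), cell_ids(m)), ,
                                       drop = FALSE])
}
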