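#' Read a count matrix from Matrix Market or dense TSV
#'
#' Matrix Market files are validated before parsing: the header dimensions
#' and entry count must match the data lines (a mismatch errors with the
#' offending line number), indices are 1-based, and values must be
#' nonnegative integers. For a dense TSV the first column is taken as gene
#' ids and the header as cell ids.
#'
#' @param path path to a `.mtx` file or a dense TSV.
#' @param genes,cells optional TSV sidecars with header line; first column
#'   is the id, optional logical columns `mito` and `reporter` (genes) and
#'   `batch` / `excluded_manually` (cells).
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, genes = NULL, cells = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  is_mtx <- grepl("\\.mtx$", path, ignore.case = TRUE) ||
    startsWith(readLines(path, n = 1L), "%%MatrixMarket")
  if (is_mtx) {
    validate_mtx(path)
    m <- as_dgc(Matrix::readMM(path))
  } else {
    tab <- utils::read.delim(path, check.names = FALSE)
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in dense TSV", call. = FALSE)
    rownames(m) <- ids
    m <- as_dgc(m)
  }
  gid <- rownames(m); cid <- colnames(m)
  mito <- NULL; reporter <- NULL; cmeta <- NULL
  if (!is.null(genes)) {
    gt <- utils::read.delim(genes)
    if (nrow(gt) != nrow(m))
      stop("genes sidecar has ", nrow(gt), " rows for ", nrow(m), " genes",
           call. = FALSE)
    gid <- as.character(gt[[1]])
    if ("mito" %in% names(gt)) mito <- as.logical(gt$mito)
    if ("reporter" %in% names(gt)) reporter <- as.logical(gt$reporter)
  }
  if (!is.null(cells)) {
    ct <- utils::read.delim(cells)
    if (nrow(ct) != ncol(m))
      stop("cells sidecar has ", nrow(ct), " rows for ", ncol(m), " cells",
           call. = FALSE)
    cid <- as.character(ct[[1]])
    cmeta <- data.frame(row.names = cid)
    if ("batch" %in% names(ct)) cmeta$batch <- as.character(ct$batch)
    if ("excluded_manually" %in% names(ct))
      cmeta$excluded_manually <- as.logical(ct$excluded_manually)
  }
  count_matrix(m, gene_ids = gid, cell_ids = cid, mito = mito,
               reporter = reporter, cell_meta = cmeta)
}

# header/shape validation so parse failures name a line, which the raw
# Matrix::readMM errors do not
validate_mtx <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "%") & nzchar(trimws(lines)))
  if (!length(body)) stop(path, ": no size line found", call. = FALSE)
  hdr_line <- body[1]
  hdr <- suppressWarnings(as.numeric(strsplit(trimws(lines[hdr_line]),
                                              "\\s+")[[1]]))
  if (length(hdr) != 3 || anyNA(hdr))
    stop(path, ": line ", hdr_line, ": malformed size line", call. = FALSE)
  nnz <- hdr[3]
  data_lines <- body[-1]
  if (length(data_lines) != nnz)
    stop(path, ": line ", hdr_line, ": header declares ", nnz,
         " entries but file has ", length(data_lines), call. = FALSE)
  if (!nnz) return(invisible(TRUE))
  f <- strsplit(trimws(lines[data_lines]), "\\s+")
  bad <- data_lines[lengths(f) != 3]
  if (length(bad))
    stop(path, ": line ", bad[1], ": malformed entry", call. = FALSE)
  v <- suppressWarnings(matrix(as.numeric(unlist(f)), ncol = 3, byrow = TRUE))
  bad <- data_lines[rowSums(is.na(v)) > 0]
  if (length(bad))
    stop(path, ": line ", bad[1], ": malformed entry", call. = FALSE)
  bad <- data_lines[v[, 1] < 1 | v[, 1] > hdr[1] | v[, 2] < 1 | v[, 2] > hdr[2]]
  if (length(bad))
    stop(path, ": line ", bad[1], ": index out of bounds", call. = FALSE)
  bad <- data_lines[v[, 3] < 0 | v[, 3] != round(v[, 3])]
  if (length(bad))
    stop(path, ": line ", bad[1], ": value is not a nonnegative integer",
         call. = FALSE)
  invisible(TRUE)
}
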