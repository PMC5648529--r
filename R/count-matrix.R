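#' UMI count matrix with per-cell metadata
#'
#' Container for a cells x genes matrix of unique molecular identifier (UMI)
#' counts together with cell and gene identifiers and per-cell metadata
#' (protocol, timepoint, and any ground-truth columns a simulator attaches).
#'
#' @param counts Non-negative integer matrix, cells in rows, genes in columns.
#' @param cell_ids Character vector of unique cell barcodes (defaults to
#'   rownames of `counts`).
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   colnames of `counts`).
#' @param cell_meta Data frame with one row per cell. A `protocol` column
#'   (one of `"DP"`, `"SP"`, `"primary"`, `"synthetic"`) and an integer
#'   `day` column are filled with defaults when absent.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (base integer matrix with dimnames), `cell_ids`, `gene_ids`, `cell_meta`.
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts), cell_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts))
    stop(sprintf("cell_ids has %d entries but matrix has %d rows",
                 length(cell_ids), nrow(counts)))
  if (length(gene_ids) != ncol(counts))
    stop(sprintf("gene_ids has %d entries but matrix has %d columns",
                 length(gene_ids), ncol(counts)))
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral UMIs")
  storage.mode(counts) <- "double"   # avoid integer overflow on pooled sums
  dimnames(counts) <- list(cell_ids, gene_ids)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(barcode = cell_ids,
                            protocol = "synthetic", day = 0L,
                            stringsAsFactors = FALSE)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != length(cell_ids))
      stop("cell_meta must have one row per cell")
    if (is.null(cell_meta$barcode)) cell_meta$barcode <- cell_ids
    if (is.null(cell_meta$protocol)) cell_meta$protocol <- "synthetic"
    if (is.null(cell_meta$day)) cell_meta$day <- 0L
  }
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes, %.0f total UMIs\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  cat("protocols:", paste(unique(x$cell_meta$protocol), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by cells
#'
#' @param m A `count_matrix`.
#' @param cells Logical, integer, or character index over cells.
#' @return A `count_matrix` restricted to the selected cells; gene set
#'   unchanged.
#' @export
subset_cells <- function(m, cells) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.character(cells)) cells <- match(cells, m$cell_ids)
  keep <- m$counts[cells, , drop = FALSE]
  meta <- m$cell_meta[cells, , drop = FALSE]
  rownames(meta) <- NULL
  count_matrix(keep, rownames(keep), m$gene_ids, meta)
}

#' Read a count matrix from disk
#'
#' Two layouts are supported: a MatrixMarket trio (`matrix.mtx` with cells in
#' rows, plus `barcodes.tsv` and `genes.tsv`, one id per line, and an optional
#' `cell_meta.tsv`), or a dense CSV with cell ids in the first column and gene
#' ids in the header.
#'
#' @param path Directory containing the mtx trio, or a CSV file path.
#' @param format `"mtx-trio"` or `"csv"`; guessed from `path` when missing.
#' @return A [count_matrix()].
#' @export
load_counts <- function(path, format = c("auto", "mtx-trio", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "mtx-trio" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    mat <- as.matrix(df)
    if (any(mat != round(mat))) stop("non-integer entries in CSV counts")
    return(count_matrix(mat, rownames(mat), colnames(mat)))
  }
  mtx <- file.path(path, "matrix.mtx")
  bc <- file.path(path, "barcodes.tsv")
  gn <- file.path(path, "genes.tsv")
  for (f in c(mtx, bc, gn)) if (!file.exists(f)) stop("missing file: ", f)
  m <- as.matrix(Matrix::readMM(mtx))
  barcodes <- readLines(bc)
  genes <- readLines(gn)
  if (length(barcodes) != nrow(m))
    stop(sprintf("dimension mismatch: %d barcodes but %d matrix rows",
                 length(barcodes), nrow(m)))
  if (length(genes) != ncol(m))
    stop(sprintf("dimension mismatch: %d genes but %d matrix columns",
                 length(genes), ncol(m)))
  meta <- NULL
  meta_path <- file.path(path, "cell_meta.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    if (!is.null(meta$barcode)) meta <- meta[match(barcodes, meta$barcode), ]
    rownames(meta) <- NULL
  }
  count_matrix(m, barcodes, genes, meta)
}

#' Write a count matrix as a MatrixMarket trio
#'
#' Writes `matrix.mtx` (cells x genes), `barcodes.tsv`, `genes.tsv`, and
#' `cell_meta.tsv` into `dir`.
#'
#' @param m A [count_matrix()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(m, dir) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- Matrix::Matrix(m$counts, sparse = TRUE)
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(m$gene_ids, file.path(dir, "genes.tsv"))
  utils::write.table(m$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Total-count-normalized expression matrix
#'
#' @param values Non-negative numeric matrix (cells x genes) whose rows each
#'   sum to `target_total`.
#' @param target_total Positive scalar; the common row total.
#' @param provenance List describing the source matrix and applied filters.
#' @return An object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, target_total, provenance = list()) {
  values <- as.matrix(values)
  rs <- rowSums(values)
  if (any(abs(rs - target_total) > 1e-6 * target_total))
    stop("row sums do not equal target_total within tolerance")
  structure(list(values = values, target_total = target_total,
                 provenance = provenance),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d genes, target total %.3g\n",
              nrow(x$values), ncol(x$values), x$target_total))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)
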