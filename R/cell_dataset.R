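#' Cell-level count dataset
#'
#' Container for a single-cell RNA-seq count matrix (cells in rows, genes in
#' columns) together with per-cell metadata. Counts are stored sparse. The
#' metadata must identify, for every cell, the single-cell sample it came from
#' and its cell type; additional columns (subject, batch, treatment, ...) are
#' carried along and become per-sample covariates after pseudobulking.
#'
#' @param counts matrix or \code{Matrix::sparseMatrix}, cells x genes,
#'   non-negative integers. Row names are cell barcodes, column names gene ids
#'   (generated when missing).
#' @param cell_meta data.frame with one row per cell; must contain columns
#'   \code{sample} and \code{celltype}.
#' @return An object of class \code{cell_dataset} with elements \code{counts}
#'   (a \code{dgCMatrix}) and \code{cell_meta}.
#' @examples
#' counts <- matrix(rpois(60, 2), nrow = 6)
#' meta <- data.frame(sample = rep(c("s1", "s2"), each = 3),
#'                    celltype = rep(c("A", "B"), 3))
#' cell_dataset(counts, meta)
#' @export
cell_dataset <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  cell_meta <- as.data.frame(cell_meta)
  if (nrow(counts) != nrow(cell_meta))
    stopf("counts has %d cells but cell_meta has %d rows",
          nrow(counts), nrow(cell_meta))
  if (nrow(counts) == 0L) stopf("dataset is empty")
  for (col in c("sample", "celltype")) {
    if (!col %in% names(cell_meta))
      stopf("cell_meta is missing required column '%s'", col)
    if (anyNA(cell_meta[[col]]))
      stopf("cell_meta column '%s' has missing values", col)
  }
  if (any(counts@x < 0)) stopf("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stopf("counts must be integers")
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("gene%04d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  rownames(cell_meta) <- rownames(counts)
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cell_dataset")
}

#' @exportS3Method base::print
print.cell_dataset <- function(x, ...) {
  cat(sprintf("cell_dataset: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  samples: %d  cell types: %d\n",
              length(unique(x$cell_meta$sample)),
              length(unique(x$cell_meta$celltype))))
  cat("  metadata columns:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

#' Write / read a cell dataset as MatrixMarket + TSV
#'
#' On disk the layout follows the common single-cell exchange convention:
#' \code{matrix.mtx} holds the counts as genes x cells, with \code{features.tsv}
#' (gene ids), \code{barcodes.tsv} (cell barcodes) and \code{cell_metadata.tsv}
#' alongside.
#'
#' @param dataset a \code{\link{cell_dataset}}.
#' @param dir directory to write to (created if needed).
#' @return \code{write_cell_dataset} returns \code{dir} invisibly;
#'   \code{read_cell_dataset} returns a \code{cell_dataset}.
#' @export
write_cell_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cell_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(dataset$counts), file.path(dir, "matrix.mtx"))
  writeLines(colnames(dataset$counts), file.path(dir, "features.tsv"))
  writeLines(rownames(dataset$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(dataset$cell_meta, file.path(dir, "cell_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cell_dataset
#' @export
read_cell_dataset <- function(dir) {
  m <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  features <- readLines(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.delim(file.path(dir, "cell_metadata.tsv"),
                            stringsAsFactors = FALSE)
  dimnames(m) <- list(barcodes, features)
  cell_dataset(m, meta)
}
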