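#' Pseudobulk aggregation of single-cell counts
#'
#' Sums cell-level counts by single-cell sample and (optionally) cell type.
#' Each observed combination becomes one pseudobulk sample; combinations with
#' zero cells are absent, never zero-filled, so with N samples and T cell
#' types the result has S <= N*T rows, with equality when every cell type is
#' observed in every sample. Aggregating \code{by = "sample"} pools all cell
#' types of a sample into one row (the per-sample matrix used by trail T3).
#'
#' Cell-level metadata columns that are constant within each output group are
#' carried over to the per-sample metadata; varying columns are dropped.
#'
#' @param dataset a \code{\link{cell_dataset}}.
#' @param by \code{"sample_celltype"} (default, role \code{Y_p}) or
#'   \code{"sample"} (role \code{Y_N}).
#' @return A \code{pseudobulk_matrix}: list with integer \code{counts}
#'   (samples x genes), \code{sample_meta} (with columns \code{sample},
#'   \code{celltype} when applicable, \code{n_cells}, and carried covariates),
#'   \code{role}, and empty normalization slots (\code{norm}, \code{logmat},
#'   \code{offsets}) to be filled by \code{\link{uq_normalize}} and
#'   \code{\link{log2p1}}.
#' @examples
#' counts <- matrix(rpois(60, 2), nrow = 6)
#' meta <- data.frame(sample = rep(c("s1", "s2"), each = 3),
#'                    celltype = rep(c("A", "B"), 3))
#' pb <- pseudobulk(cell_dataset(counts, meta))
#' pb$counts
#' @export
pseudobulk <- function(dataset, by = c("sample_celltype", "sample")) {
  stopifnot(inherits(dataset, "cell_dataset"))
  by <- match.arg(by)
  meta <- dataset$cell_meta
  if (by == "sample_celltype") {
    key <- interaction(meta$sample, meta$celltype, sep = ".", drop = TRUE)
    role <- "Y_p"
  } else {
    key <- factor(meta$sample)
    role <- "Y_N"
  }
  groups <- levels(key)
  # sparse indicator (cells x groups); group sums by one crossprod
  ind <- Matrix::sparseMatrix(i = seq_along(key), j = as.integer(key),
                              x = 1, dims = c(length(key), length(groups)))
  counts <- as.matrix(Matrix::crossprod(ind, dataset$counts))
  rownames(counts) <- groups

  idx <- split(seq_along(key), key)
  carried <- vapply(names(meta), function(col) {
    all(vapply(idx, function(i) length(unique(meta[[col]][i])) == 1L, TRUE))
  }, TRUE)
  sample_meta <- data.frame(row.names = groups)
  sample_meta$sample <- vapply(idx, function(i) as.character(meta$sample[i[1]]), "")
  if (by == "sample_celltype")
    sample_meta$celltype <- vapply(idx, function(i) as.character(meta$celltype[i[1]]), "")
  for (col in setdiff(names(meta)[carried], c("sample", "celltype")))
    sample_meta[[col]] <- vapply(idx, function(i) as.character(meta[[col]][i[1]]), "")
  sample_meta$n_cells <- lengths(idx)

  structure(list(counts = counts, sample_meta = sample_meta, role = role,
                 norm = NULL, logmat = NULL, offsets = NULL),
            class = "pseudobulk_matrix")
}

#' @exportS3Method base::print
print.pseudobulk_matrix <- function(x, ...) {
  cat(sprintf("pseudobulk_matrix (role %s): %d samples x %d genes\n",
              x$role, nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  normalized: %s  log2: %s\n",
              !is.null(x$norm), !is.null(x$logmat)))
  invisible(x)
}

#' @export
dim.pseudobulk_matrix <- function(x) dim(x$counts)

#' Upper-quartile normalization
#'
#' Scales each pseudobulk sample by the 75th percentile of its non-zero
#' counts. Factors are rescaled to geometric mean 1 so the overall count
#' scale is preserved; after normalization the per-sample upper quartiles of
#' non-zero values are equal.
#'
#' @param pb a \code{pseudobulk_matrix}.
#' @return \code{pb} with \code{norm} (normalized matrix) and \code{offsets}
#'   (per-sample scale factors, geometric mean 1) filled.
#' @export
uq_normalize <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk_matrix"))
  counts <- pb$counts
  uq <- apply(counts, 1, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0L) NA_real_ else quantile(nz, 0.75, names = FALSE)
  })
  if (anyNA(uq))
    stopf("sample(s) with all-zero counts: %s",
          paste(rownames(counts)[is.na(uq)], collapse = ", "))
  offsets <- uq / geometric_mean(uq)
  pb$norm <- counts / offsets
  pb$offsets <- setNames(offsets, rownames(counts))
  pb
}

#' Log2 transform with pseudo-count
#'
#' Fills \code{logmat = log2(x + 1)} where \code{x} is the UQ-normalized
#' matrix when present, otherwise the raw counts. The pseudo-count avoids
#' logarithms of zero. A second call on an already-transformed object is a
#' no-op, so the transform cannot be applied twice.
#'
#' @param pb a \code{pseudobulk_matrix}.
#' @return \code{pb} with \code{logmat} filled.
#' @export
log2p1 <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk_matrix"))
  if (!is.null(pb$logmat)) return(pb)
  x <- pb$norm %||% pb$counts
  if (any(x < 0)) stopf("negative entries; cannot log-transform")
  pb$logmat <- log2(x + 1)
  pb
}

#' Read / write pseudobulk matrices as CSV
#'
#' \code{write_pseudobulk} writes \code{<prefix>_counts.csv},
#' \code{<prefix>_meta.csv} and, when present, \code{<prefix>_offsets.csv}.
#' \code{read_pseudobulk} accepts a pre-aggregated samples x genes count table
#' plus sample metadata and returns a \code{pseudobulk_matrix}.
#'
#' @param pb a \code{pseudobulk_matrix}.
#' @param prefix path prefix for output files.
#' @export
write_pseudobulk <- function(pb, prefix) {
  stopifnot(inherits(pb, "pseudobulk_matrix"))
  utils::write.csv(pb$counts, paste0(prefix, "_counts.csv"))
  utils::write.csv(pb$sample_meta, paste0(prefix, "_meta.csv"))
  if (!is.null(pb$offsets))
    utils::write.csv(data.frame(sample = names(pb$offsets),
                                offset = unname(pb$offsets)),
                     paste0(prefix, "_offsets.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_pseudobulk
#' @param counts_csv,meta_csv paths to samples x genes counts (first column =
#'   sample id) and sample metadata CSVs.
#' @param role matrix role, \code{"Y_p"}, \code{"Y_t"} or \code{"Y_N"}.
#' @export
read_pseudobulk <- function(counts_csv, meta_csv, role = "Y_p") {
  counts <- as.matrix(utils::read.csv(counts_csv, row.names = 1,
                                      check.names = FALSE))
  meta <- utils::read.csv(meta_csv, row.names = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopifnot(nrow(counts) == nrow(meta))
  structure(list(counts = counts, sample_meta = meta, role = role,
                 norm = NULL, logmat = NULL, offsets = NULL),
            class = "pseudobulk_matrix")
}
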