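# Pseudobulk pseudosamples (PBPS).
#
# PBPS are artificial pseudobulk samples built by resampling cells with
# replacement within strata defined by (biology b) x (known unwanted
# variation l). Pseudosamples that share b but differ in l behave as
# technical replicates whose differences are (by assumption) unwanted
# variation, which makes RUVIII applicable with all genes as negative
# controls when no real technical replicates exist. Three assumptions:
# at least one technical covariate is known; cells with the same biology
# and technical exposure are exchangeable; and differences between
# same-biology pseudosamples across technical levels are mainly unwanted
# variation.

#' PBPS configuration
#'
#' @param bio_covariates cell-metadata columns defining the biological
#'   subgroups b (e.g. treatment, ethnicity, cell type). Must include the
#'   cell type column for \code{\link{ruviii_pbps}}.
#' @param uv_covariates cell-metadata columns defining the known
#'   unwanted-variation levels l (e.g. processing batch). Disjoint from
#'   \code{bio_covariates}.
#' @param n_pseudosamples pseudosamples I drawn per non-empty (b, l) stratum.
#' @param rounding how the fractional average cells-per-sample \code{c_bar}
#'   becomes a resample size: \code{"round"} (default), \code{"floor"} or
#'   \code{"ceiling"}; always at least 1.
#' @param seed RNG seed for the resampling.
#' @return A \code{pbps_config} list.
#' @export
pbps_config <- function(bio_covariates, uv_covariates,
                        n_pseudosamples = 10,
                        rounding = c("round", "floor", "ceiling"),
                        seed = 1) {
  rounding <- match.arg(rounding)
  if (length(intersect(bio_covariates, uv_covariates)) > 0)
    stopf("bio and uv covariates must be disjoint")
  if (n_pseudosamples < 1) stopf("n_pseudosamples must be >= 1")
  structure(list(bio_covariates = bio_covariates,
                 uv_covariates = uv_covariates,
                 n_pseudosamples = n_pseudosamples,
                 rounding = rounding, seed = seed),
            class = "pbps_config")
}

#' Stratify cells into biology and unwanted-variation groups
#'
#' Assigns every cell to a biological subgroup b (the crossing of the
#' biological covariates) and, within it, an unwanted-variation level l (the
#' crossing of the technical covariates), and computes \code{c_bar[b]}: the
#' average number of cells per contributing single-cell sample within each
#' biological subgroup, at full precision (printed to one decimal).
#'
#' @param dataset a \code{\link{cell_dataset}}.
#' @param config a \code{\link{pbps_config}}.
#' @return A \code{pbps_grouping}: per-cell factors \code{bio} and \code{uv},
#'   the named vector \code{cbar}, and a table of subgroup covariate values.
#' @export
define_groups <- function(dataset, config) {
  stopifnot(inherits(dataset, "cell_dataset"), inherits(config, "pbps_config"))
  meta <- dataset$cell_meta
  for (col in c(config$bio_covariates, config$uv_covariates)) {
    if (!col %in% names(meta)) stopf("cell metadata is missing column '%s'", col)
    if (anyNA(meta[[col]]))
      stopf("covariate '%s' has missing values for cells: %s", col,
            paste(head(rownames(meta)[is.na(meta[[col]])], 5), collapse = ", "))
  }
  bio <- interaction(meta[config$bio_covariates], sep = "|", drop = TRUE)
  uv <- interaction(meta[config$uv_covariates], sep = "|", drop = TRUE)
  cbar <- vapply(split(as.character(meta$sample), bio), function(s) {
    length(s) / length(unique(s))
  }, 0)
  bio_table <- unique(cbind(meta[config$bio_covariates],
                            b = as.character(bio)))
  rownames(bio_table) <- NULL
  structure(list(bio = bio, uv = uv, cbar = cbar,
                 bio_table = bio_table, config = config),
            class = "pbps_grouping")
}

#' @exportS3Method base::print
print.pbps_grouping <- function(x, ...) {
  cat(sprintf("pbps_grouping: B = %d biological subgroups x L = %d UV levels\n",
              nlevels(x$bio), nlevels(x$uv)))
  cat("  average cells per sample (c_bar):\n")
  print(round(x$cbar, 1))
  invisible(x)
}

#' Generate pseudobulk pseudosamples
#'
#' For every non-empty stratum (b, l), draws \code{I} cell multisets of size
#' \code{c_bar[b]} (rounded, minimum 1) uniformly with replacement and sums
#' their count vectors into pseudosamples. Pseudosamples may mix cells from
#' different single-cell samples of the stratum. The result appends the
#' pseudosamples to the original samples-by-cell-type pseudobulk matrix,
#' leaving original rows untouched.
#'
#' @param dataset a \code{\link{cell_dataset}}.
#' @param config a \code{\link{pbps_config}}.
#' @param grouping optional \code{\link{define_groups}} result (recomputed if
#'   missing).
#' @return A \code{pbps_result}: \code{augmented} (a
#'   \code{pseudobulk_matrix} of size (S + S') x G), \code{pbps_meta}
#'   (pseudosample table with b, l, draw index i, resample size, covariate
#'   values, and contributing cell ids), and \code{origin_mask}
#'   (\code{TRUE} for original rows).
#' @export
generate_pbps <- function(dataset, config, grouping = NULL) {
  stopifnot(inherits(dataset, "cell_dataset"), inherits(config, "pbps_config"))
  if (is.null(grouping)) grouping <- define_groups(dataset, config)
  set.seed(config$seed)
  meta <- dataset$cell_meta
  sizes <- pmax(1L, as.integer(switch(config$rounding,
    round = round(grouping$cbar),
    floor = floor(grouping$cbar),
    ceiling = ceiling(grouping$cbar))))
  names(sizes) <- names(grouping$cbar)

  combos <- expand.grid(b = levels(grouping$bio), l = levels(grouping$uv),
                        stringsAsFactors = FALSE)
  cells_of <- split(seq_len(nrow(meta)),
                    list(grouping$bio, grouping$uv), sep = "\f")
  counts_list <- list()
  meta_rows <- list()
  empty <- character(0)
  I <- config$n_pseudosamples
  for (j in seq_len(nrow(combos))) {
    b <- combos$b[j]; l <- combos$l[j]
    pool <- cells_of[[paste(b, l, sep = "\f")]]
    if (is.null(pool) || length(pool) == 0L) {
      empty <- c(empty, sprintf("(%s, %s)", b, l))
      next
    }
    for (i in seq_len(I)) {
      draw <- pool[sample.int(length(pool), sizes[[b]], replace = TRUE)]
      v <- Matrix::colSums(dataset$counts[draw, , drop = FALSE])
      id <- sprintf("pbps|%s|%s|%d", b, l, i)
      counts_list[[id]] <- v
      meta_rows[[id]] <- data.frame(
        id = id, b = b, l = l, i = i, size = sizes[[b]],
        cells = paste(rownames(meta)[draw], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(empty) > 0)
    warnf("%d empty (b, l) strata generate no pseudosamples: %s",
          length(empty), paste(head(empty, 5), collapse = ", "))
  if (length(counts_list) == 0L) stopf("no non-empty (b, l) strata")

  pbps_counts <- do.call(rbind, counts_list)
  pbps_meta <- do.call(rbind, meta_rows)
  # unpack the covariate values encoded in b and l
  bio_vals <- do.call(rbind, strsplit(pbps_meta$b, "|", fixed = TRUE))
  colnames(bio_vals) <- config$bio_covariates
  uv_vals <- do.call(rbind, strsplit(pbps_meta$l, "|", fixed = TRUE))
  colnames(uv_vals) <- config$uv_covariates
  pbps_meta <- cbind(pbps_meta, bio_vals, uv_vals, stringsAsFactors = FALSE)
  rownames(pbps_meta) <- pbps_meta$id

  orig <- pseudobulk(dataset, by = "sample_celltype")
  aug_counts <- rbind(orig$counts, pbps_counts)
  aug_meta <- orig$sample_meta
  add <- data.frame(row.names = pbps_meta$id)
  add$sample <- pbps_meta$id
  for (col in setdiff(names(aug_meta), c("sample", "n_cells")))
    add[[col]] <- if (col %in% colnames(bio_vals)) pbps_meta[[col]]
                  else if (col %in% colnames(uv_vals)) pbps_meta[[col]]
                  else NA_character_
  add$n_cells <- pbps_meta$size
  aug_meta <- rbind(aug_meta, add[names(aug_meta)])
  augmented <- structure(list(counts = aug_counts, sample_meta = aug_meta,
                              role = "Y_p", norm = NULL, logmat = NULL,
                              offsets = NULL),
                         class = "pseudobulk_matrix")
  structure(list(augmented = augmented, pbps_meta = pbps_meta,
                 origin_mask = c(rep(TRUE, nrow(orig$counts)),
                                 rep(FALSE, nrow(pbps_counts))),
                 grouping = grouping, config = config),
            class = "pbps_result")
}

#' @exportS3Method base::print
print.pbps_result <- function(x, ...) {
  cat(sprintf("pbps_result: %d original + %d pseudosamples x %d genes\n",
              sum(x$origin_mask), sum(!x$origin_mask),
              ncol(x$augmented$counts)))
  invisible(x)
}

#' Replicate structure over an augmented PBPS matrix
#'
#' Pseudosamples sharing a biological subgroup b form one replicate group
#' (across unwanted-variation levels and draws), so their differences encode
#' unwanted variation; each original sample is its own singleton group unless
#' real technical-replicate labels are supplied for the originals.
#'
#' @param result a \code{pbps_result}.
#' @param replicate_labels optional named vector (single-cell sample id ->
#'   replicate group) honored for original rows.
#' @return Binary membership matrix over the (S + S') augmented rows, for
#'   \code{\link{ruviii}}.
#' @export
pbps_replicate_structure <- function(result, replicate_labels = NULL) {
  stopifnot(inherits(result, "pbps_result"))
  meta <- result$augmented$sample_meta
  rows <- rownames(meta)
  labels <- character(nrow(meta))
  orig <- result$origin_mask
  labels[orig] <- if (is.null(replicate_labels)) rows[orig] else {
    lab <- replicate_labels[as.character(meta$sample[orig])]
    ifelse(is.na(lab), rows[orig], paste0("rep:", lab))
  }
  labels[!orig] <- paste0("pbps:", result$pbps_meta$b)
  make_replicate_matrix(setNames(labels, rows))
}

#' RUVIII with pseudobulk pseudosamples, per cell type
#'
#' The RUVIII-PBPS workflow: for every cell type, the original pseudobulk
#' samples of that cell type are augmented with its pseudosamples,
#' UQ-normalized jointly and log2-transformed; RUVIII is run with all genes
#' as negative controls and the PBPS replicate structure; the pseudosample
#' rows are then discarded, returning only the factor rows of the original
#' samples for the DEA. The cell type must be one of the biological
#' covariates so pseudosamples are cell-type specific.
#'
#' @param dataset a \code{\link{cell_dataset}}.
#' @param config a \code{\link{pbps_config}} whose \code{bio_covariates}
#'   include \code{celltype_col}.
#' @param k number of unwanted factors (3 by default, the usual
#'   case-study-scale choice).
#' @param celltype_col cell type column name.
#' @param result optional pre-computed \code{\link{generate_pbps}} result.
#' @param replicate_labels optional real technical-replicate labels for the
#'   original samples (see \code{\link{pbps_replicate_structure}}).
#' @return Named list (cell type -> \code{W_t}, original samples only, rows
#'   named by \code{Y_p} row ids), with attribute \code{"fits"}.
#' @export
ruviii_pbps <- function(dataset, config, k = 3, celltype_col = "celltype",
                        result = NULL, replicate_labels = NULL) {
  stopifnot(inherits(config, "pbps_config"))
  if (!celltype_col %in% config$bio_covariates)
    stopf("'%s' must be among the PBPS biological covariates", celltype_col)
  if (is.null(result)) result <- generate_pbps(dataset, config)
  aug <- result$augmented
  meta <- aug$sample_meta
  orig <- result$origin_mask
  M_all <- pbps_replicate_structure(result, replicate_labels)
  celltypes <- sort(unique(as.character(meta[[celltype_col]][orig])))
  res <- list()
  fits <- list()
  for (t in celltypes) {
    rows <- which(as.character(meta[[celltype_col]]) == t)
    if (!any(!orig[rows]))
      stopf("cell type '%s' has no pseudosamples", t)
    pb_t <- structure(list(counts = aug$counts[rows, , drop = FALSE],
                           sample_meta = meta[rows, , drop = FALSE],
                           role = "Y_t", norm = NULL, logmat = NULL,
                           offsets = NULL),
                      class = "pseudobulk_matrix")
    pb_t <- log2p1(uq_normalize(pb_t))
    M_t <- M_all[rows, , drop = FALSE]
    M_t <- M_t[, colSums(M_t) > 0, drop = FALSE]
    fit <- ruviii(pb_t$logmat, M_t, rep(TRUE, ncol(aug$counts)), k)$fit
    keep <- orig[rows]
    W <- fit$W[keep, , drop = FALSE]
    rownames(W) <- rownames(aug$counts)[rows][keep]
    res[[t]] <- W
    fits[[t]] <- fit
  }
  attr(res, "fits") <- fits
  res
}
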