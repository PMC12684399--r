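# Trails: strategies for applying a RUV estimator to pseudobulk data.
#
# T1 runs the estimator once on the full samples-by-cell-type matrix Y_p and
# partitions W by cell type afterwards (samples treated as independent even
# though pseudobulk samples from one single-cell sample are correlated).
# T2 runs it independently per cell type, so all rows within a fit are
# independent. T3 aggregates counts per single-cell sample (cell types
# pooled), estimates W_N once, and broadcasts row n of W_N to every
# pseudobulk sample (n, t) -- assuming technical noise does not interact with
# cell type.

#' Trail specification
#'
#' @param trail \code{"T1"} (all samples), \code{"T2"} (per cell type) or
#'   \code{"T3"} (per single-cell sample).
#' @param method \code{"RUV2"}, \code{"RUV4"} or \code{"RUVIII"}.
#' @param k number of unwanted factors (the simulation analyses here default
#'   to 5; 3 is typical for case-study-sized fits).
#' @param ctl negative-control gene mask or indices (see \code{\link{ruv2}}).
#' @param factor_of_interest,celltype_col names of the metadata columns
#'   holding the tested covariate and the cell type.
#' @param replicate_labels RUVIII only: named vector mapping single-cell
#'   sample ids to replicate groups (e.g. subject ids). Under T1 the groups
#'   become replicate-by-cell-type, under T2 they are used within each cell
#'   type, under T3 as given.
#' @param condition_on_design RUV2 only: residualize control genes on the
#'   trail design before the factor analysis instead of simply centering
#'   them. Default \code{FALSE} (controls are assumed unaffected by the
#'   design).
#' @return A \code{trail_spec} list.
#' @export
trail_spec <- function(trail = c("T1", "T2", "T3"),
                       method = c("RUV2", "RUV4", "RUVIII"),
                       k = 5, ctl,
                       factor_of_interest = "treatment",
                       celltype_col = "celltype",
                       replicate_labels = NULL,
                       condition_on_design = FALSE) {
  trail <- match.arg(trail)
  method <- match.arg(method)
  if (k < 1) stopf("k must be >= 1")
  if (method == "RUVIII" && is.null(replicate_labels))
    stopf("RUVIII requires replicate_labels (negative control samples)")
  structure(list(trail = trail, method = method, k = k, ctl = ctl,
                 factor_of_interest = factor_of_interest,
                 celltype_col = celltype_col,
                 replicate_labels = replicate_labels,
                 condition_on_design = condition_on_design),
            class = "trail_spec")
}

#' Cell-means design for trail T1
#'
#' Builds the S x Q matrix of dummy regressors coding the observed
#' combinations of cell type and factor-of-interest level (one indicator per
#' combination, no intercept; interactions are implicit in the crossing).
#'
#' @param sample_meta pseudobulk sample metadata.
#' @param factor_of_interest,celltype_col column names.
#' @return Full-rank indicator matrix, one column per observed combination.
#' @export
build_design_T1 <- function(sample_meta, factor_of_interest = "treatment",
                            celltype_col = "celltype") {
  for (col in c(factor_of_interest, celltype_col))
    if (!col %in% names(sample_meta))
      stopf("sample_meta is missing column '%s'", col)
  f <- droplevels(interaction(sample_meta[[celltype_col]],
                              sample_meta[[factor_of_interest]],
                              sep = ":", drop = TRUE))
  V <- model.matrix(~ 0 + f)
  colnames(V) <- levels(f)
  rownames(V) <- rownames(sample_meta)
  if (anyDuplicated(t(V))) stopf("duplicated design columns")
  if (qr(V)$rank < ncol(V)) stopf("T1 design is rank deficient")
  V
}

#' Estimate unwanted factors under a trail
#'
#' Applies the chosen RUV estimator to a (UQ-normalized, log2) pseudobulk
#' matrix following the trail in \code{spec}, and returns one factor matrix
#' \code{W_t} per cell type, rows aligned (and named) to the corresponding
#' rows of \code{Y_p}, ready to be passed to \code{\link{fit_dea}}.
#'
#' Under T2, a cell type with fewer samples than \code{k + Q} (Q = design
#' columns) is skipped with a warning and recorded in the
#' \code{"skipped"} attribute. Under T3 every pseudobulk sample of a
#' single-cell sample receives that sample's row of \code{W_N}.
#'
#' @param pb a \code{pseudobulk_matrix} with role \code{Y_p}; UQ
#'   normalization and log2 transform are applied if not already present.
#' @param spec a \code{\link{trail_spec}}.
#' @param dataset the underlying \code{\link{cell_dataset}}; required for T3
#'   unless \code{pb_sample} is given.
#' @param pb_sample optional pre-computed per-sample matrix (role
#'   \code{Y_N}) for T3.
#' @return Named list (cell type -> \code{W_t} matrix with rownames equal to
#'   the \code{Y_p} row ids), with attributes \code{"fits"} (the underlying
#'   \code{ruv_fit} objects) and \code{"skipped"}.
#' @export
estimate_W <- function(pb, spec, dataset = NULL, pb_sample = NULL) {
  stopifnot(inherits(pb, "pseudobulk_matrix"), inherits(spec, "trail_spec"))
  if (is.null(pb$logmat)) pb <- log2p1(uq_normalize(pb))
  Yl <- pb$logmat
  meta <- pb$sample_meta
  ct <- as.character(meta[[spec$celltype_col]])
  foi <- factor(meta[[spec$factor_of_interest]])
  celltypes <- sort(unique(ct))
  skipped <- character(0)

  rep_groups <- function(samples, with_ct = NULL) {
    lab <- spec$replicate_labels[as.character(samples)]
    if (anyNA(lab)) stopf("replicate_labels missing for some samples")
    if (!is.null(with_ct)) lab <- paste(lab, with_ct, sep = ":")
    lab
  }

  if (spec$trail == "T1") {
    fit <- switch(spec$method,
      RUV2 = {
        des <- if (spec$condition_on_design)
          build_design_T1(meta, spec$factor_of_interest, spec$celltype_col)
        ruv2(Yl, spec$ctl, spec$k, design = des)
      },
      RUV4 = ruv4(Yl, build_design_T1(meta, spec$factor_of_interest,
                                      spec$celltype_col),
                  spec$ctl, spec$k),
      RUVIII = ruviii(Yl, make_replicate_matrix(rep_groups(meta$sample, ct)),
                      spec$ctl, spec$k)$fit
    )
    W <- fit$W
    rownames(W) <- rownames(Yl)
    res <- lapply(setNames(celltypes, celltypes),
                  function(t) W[ct == t, , drop = FALSE])
    fits <- list(T1 = fit)
  } else if (spec$trail == "T2") {
    res <- list()
    fits <- list()
    for (t in celltypes) {
      rows <- which(ct == t)
      foi_t <- droplevels(foi[rows])
      Q <- nlevels(foi_t)
      if (length(rows) < spec$k + Q) {
        warnf("cell type '%s' has %d samples (< k + Q = %d); skipped",
              t, length(rows), spec$k + Q)
        skipped <- c(skipped, t)
        next
      }
      Yt <- Yl[rows, , drop = FALSE]
      fit <- switch(spec$method,
        RUV2 = ruv2(Yt, spec$ctl, spec$k,
                    design = if (spec$condition_on_design)
                      model.matrix(~ foi_t)),
        RUV4 = ruv4(Yt, model.matrix(~ foi_t), spec$ctl, spec$k),
        RUVIII = ruviii(Yt, make_replicate_matrix(rep_groups(meta$sample[rows])),
                        spec$ctl, spec$k)$fit
      )
      W <- fit$W
      rownames(W) <- rownames(Yl)[rows]
      res[[t]] <- W
      fits[[t]] <- fit
    }
  } else { # T3
    if (is.null(pb_sample)) {
      if (is.null(dataset))
        stopf("T3 requires `dataset` or a pre-computed `pb_sample` (Y_N)")
      pb_sample <- pseudobulk(dataset, by = "sample")
    }
    if (is.null(pb_sample$logmat))
      pb_sample <- log2p1(uq_normalize(pb_sample))
    Yn <- pb_sample$logmat
    meta_n <- pb_sample$sample_meta
    foi_n <- factor(meta_n[[spec$factor_of_interest]])
    fit <- switch(spec$method,
      RUV2 = ruv2(Yn, spec$ctl, spec$k,
                  design = if (spec$condition_on_design) model.matrix(~ foi_n)),
      RUV4 = ruv4(Yn, model.matrix(~ foi_n), spec$ctl, spec$k),
      RUVIII = ruviii(Yn, make_replicate_matrix(rep_groups(meta_n$sample)),
                      spec$ctl, spec$k)$fit
    )
    Wn <- fit$W
    idx <- match(as.character(meta$sample), as.character(meta_n$sample))
    if (anyNA(idx))
      stopf("sample(s) in Y_p missing from Y_N: %s",
            paste(unique(meta$sample[is.na(idx)]), collapse = ", "))
    res <- lapply(setNames(celltypes, celltypes), function(t) {
      rows <- which(ct == t)
      W <- Wn[idx[rows], , drop = FALSE]
      rownames(W) <- rownames(Yl)[rows]
      W
    })
    fits <- list(T3 = fit)
  }
  attr(res, "fits") <- fits
  attr(res, "skipped") <- skipped
  res
}
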