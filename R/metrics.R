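# Diagnostics and benchmarking metrics: relative log expression (RLE),
# average silhouette width (ASW) on principal components, TPR/FDR against
# simulation truth, and association of estimated factors with known
# unwanted-variation labels.

#' Relative log expression statistics
#'
#' RLE removes each gene's median (across samples) from the log2 matrix;
#' well-normalized data shows per-sample RLE distributions centred at zero
#' with similar spreads.
#'
#' @param Ylog numeric matrix, m samples x G genes, log2 scale.
#' @return data.frame with per-sample \code{median} and \code{iqr} of the
#'   RLE; the full RLE matrix is in attribute \code{"rle"}.
#' @export
rle_stats <- function(Ylog) {
  Ylog <- as.matrix(Ylog)
  if (nrow(Ylog) < 2) stopf("need at least 2 samples")
  rle <- sweep(Ylog, 2, apply(Ylog, 2, median))
  out <- data.frame(sample = rownames(Ylog) %||% seq_len(nrow(Ylog)),
                    median = apply(rle, 1, median),
                    iqr = apply(rle, 1, IQR),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "rle") <- rle
  out
}

#' Average silhouette width of samples in PC space
#'
#' Gene-centers the matrix, projects onto the top principal components, and
#' scores how strongly the samples cluster by \code{labels} (Euclidean
#' silhouette). ASW near 0 means the labels do not structure the data; large
#' positive ASW for a batch label indicates uncorrected unwanted variation.
#'
#' @param Y numeric matrix, m samples x G genes (log2 or normalized log2).
#' @param labels per-sample grouping (e.g. batch), at least 2 distinct
#'   values.
#' @param n_pcs number of principal components (2 and 10 are the usual
#'   choices); capped at the available rank.
#' @return list with \code{asw} (mean silhouette width), \code{widths}
#'   (per-sample), \code{labels}, \code{n_pcs}.
#' @export
asw <- function(Y, labels, n_pcs = 10) {
  Y <- as.matrix(Y)
  f <- factor(labels)
  if (nlevels(f) < 2) stopf("need at least 2 distinct labels")
  if (length(f) != nrow(Y)) stopf("labels length must match rows of Y")
  n_pcs <- min(n_pcs, nrow(Y) - 1L, ncol(Y))
  pcs <- prcomp(Y, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  sil <- cluster::silhouette(as.integer(f), dist(pcs))
  widths <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, nrow(Y))
  list(asw = mean(widths),
       widths = setNames(widths, rownames(Y)),
       labels = f, n_pcs = n_pcs)
}

#' True positive rate and false discovery rate of a gene call set
#'
#' \code{TPR = |called & truth| / |truth|};
#' \code{FDR = |called \ truth| / max(|called|, 1)} (an empty call set has
#' FDR 0). An empty truth set yields \code{TPR = NA}.
#'
#' @param called,truth character vectors of gene ids.
#' @return named numeric vector \code{c(tpr, fdr)}.
#' @export
tpr_fdr <- function(called, truth) {
  called <- unique(called)
  truth <- unique(truth)
  tp <- length(intersect(called, truth))
  tpr <- if (length(truth) == 0) NA_real_ else tp / length(truth)
  fdr <- (length(called) - tp) / max(length(called), 1)
  c(tpr = tpr, fdr = fdr)
}

#' Association of estimated unwanted factors with known labels
#'
#' For every column of W: a Kruskal-Wallis test of the factor across the
#' label classes, and the coefficient of determination (R^2) of the OLS of
#' the factor on the label dummies. Both per-factor values and their
#' max/mean are reported (the aggregation across factors is reported
#' explicitly, never collapsed silently).
#'
#' @param W numeric matrix, m samples x K factors.
#' @param labels per-sample grouping with >= 2 classes.
#' @return list with \code{per_factor} (data.frame: factor, kw_p, r2),
#'   \code{max_r2}, \code{mean_r2}, \code{min_kw_p}.
#' @export
w_association <- function(W, labels) {
  W <- cbind(W)
  f <- factor(labels)
  if (nlevels(f) < 2) stopf("need at least 2 label classes")
  if (length(f) != nrow(W)) stopf("labels length must match rows of W")
  res <- lapply(seq_len(ncol(W)), function(k) {
    w <- W[, k]
    if (var(w) < 1e-300) {
      warnf("factor %d is constant; Kruskal-Wallis p set to 1", k)
      return(c(kw_p = 1, r2 = 0))
    }
    kw <- kruskal.test(w, f)$p.value
    r2 <- summary(lm(w ~ f))$r.squared
    c(kw_p = kw, r2 = r2)
  })
  per <- data.frame(factor = seq_len(ncol(W)), do.call(rbind, res))
  list(per_factor = per, max_r2 = max(per$r2), mean_r2 = mean(per$r2),
       min_kw_p = min(per$kw_p))
}
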