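# Per-cell-type differential expression on log2 pseudobulk data:
# gene-wise least squares of log2(Y_t) on [X | W_t], with the estimated
# unwanted factors as covariates, an optional limma-style empirical-Bayes
# variance moderation, and Benjamini-Hochberg adjustment within cell type.

#' Differential expression with unwanted factors as covariates
#'
#' Fits, for every gene, the linear model
#' \code{log2(Y_t) = X beta_t + W_t alpha_t + eps} by ordinary least squares
#' and tests the contrast of interest with a (optionally moderated) t-test
#' with \code{S_t - Q - K} residual degrees of freedom. Moderation shrinks
#' the gene-wise residual variances toward a common prior
#' (\code{limma::squeezeVar}) and adds the prior degrees of freedom to the
#' test, as in the moderated t-statistic.
#'
#' @param Yt_log numeric matrix, S_t samples x G genes, log2 scale (one cell
#'   type).
#' @param X design matrix S_t x Q for the factors of interest (include the
#'   intercept here).
#' @param W optional S_t x K matrix of estimated unwanted factors, rows
#'   aligned with \code{Yt_log}.
#' @param contrast the tested effect: a column name of \code{X}, or a
#'   numeric vector of length \code{ncol(X)} (or \code{ncol(X) + ncol(W)}).
#' @param moderate logical, empirical-Bayes variance moderation (default
#'   \code{TRUE}).
#' @return A \code{dea_result} data.frame with one row per gene: \code{gene},
#'   \code{logFC} (effect on the log2 scale), \code{se}, \code{t},
#'   \code{p.value}, \code{q.value} (BH). The model descriptor (covariates,
#'   df, moderation) is stored in attribute \code{"model"}.
#' @examples
#' y <- matrix(rnorm(60), 6, 10)
#' X <- cbind(1, rep(0:1, each = 3))
#' colnames(X) <- c("(Intercept)", "group")
#' fit_dea(y, X, contrast = "group", moderate = FALSE)
#' @export
fit_dea <- function(Yt_log, X, W = NULL, contrast, moderate = TRUE) {
  Y <- as.matrix(Yt_log)
  X <- cbind(X)
  if (!is.null(W)) {
    W <- cbind(W)
    if (nrow(W) != nrow(Y)) stopf("W has %d rows but Yt_log has %d",
                                  nrow(W), nrow(Y))
    if (is.null(colnames(W))) colnames(W) <- paste0("W", seq_len(ncol(W)))
  }
  D <- if (is.null(W)) X else cbind(X, W)
  n <- nrow(Y)
  p <- ncol(D)
  if (n <= p) stopf("need more samples (%d) than design columns (%d)", n, p)
  qrD <- qr(D)
  if (qrD$rank < p) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1):p]]
    stopf("design is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  cvec <- if (is.character(contrast)) {
    if (!contrast %in% colnames(D)) stopf("contrast '%s' not in design", contrast)
    as.numeric(colnames(D) == contrast)
  } else {
    if (length(contrast) == ncol(X)) c(contrast, rep(0, p - ncol(X)))
    else if (length(contrast) == p) as.numeric(contrast)
    else stopf("contrast length must be ncol(X) or ncol(X) + ncol(W)")
  }

  XtXi <- chol2inv(chol(crossprod(D)))
  B <- XtXi %*% crossprod(D, Y)
  effect <- drop(crossprod(cvec, B))
  res <- Y - D %*% B
  df <- n - p
  s2 <- colSums(res^2) / df
  # numerically-perfect fits: residual variance is rounding noise, not signal
  zero_var <- s2 < 1e-20 * (colMeans(Y * Y) + 1e-8)
  vc <- drop(t(cvec) %*% XtXi %*% cvec)

  if (moderate) {
    sq <- limma::squeezeVar(s2, df)
    s2_used <- sq$var.post
    df_used <- df + sq$df.prior
  } else {
    s2_used <- s2
    df_used <- df
  }
  se <- sqrt(vc * s2_used)
  tstat <- effect / se
  pval <- 2 * pt(-abs(tstat), df = df_used)
  null_eff <- abs(effect) < 1e-10 * sqrt(colMeans(Y * Y) + 1e-8)
  tstat[zero_var] <- ifelse(null_eff[zero_var], 0, Inf * sign(effect[zero_var]))
  pval[zero_var] <- ifelse(null_eff[zero_var], 1, 0)
  qval <- p.adjust(pval, method = "BH")

  out <- data.frame(gene = colnames(Y) %||% sprintf("gene%04d", seq_len(ncol(Y))),
                    logFC = effect, se = se, t = tstat,
                    p.value = pval, q.value = qval,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("dea_result", "data.frame")
  attr(out, "model") <- list(
    covariates = colnames(D),
    n_unwanted = if (is.null(W)) 0L else ncol(W),
    df_residual = df, moderated = moderate,
    df_used = if (moderate) df_used else df)
  out
}

#' Call differentially expressed genes at a nominal FDR level
#'
#' @param result a \code{\link{fit_dea}} result.
#' @param level nominal FDR level in (0, 1].
#' @return Character vector of gene ids with BH-adjusted q-value <= level.
#' @export
call_deg <- function(result, level = 0.05) {
  stopifnot(inherits(result, "dea_result"))
  if (level <= 0 || level > 1) stopf("level must be in (0, 1]")
  result$gene[result$q.value <= level]
}

#' Write a DEA result with its model descriptor
#'
#' Writes \code{<prefix>.csv} (gene, logFC, t, p, q) and
#' \code{<prefix>_model.json} (covariates, degrees of freedom, moderation).
#'
#' @param result a \code{dea_result}.
#' @param prefix output path prefix.
#' @export
write_dea <- function(result, prefix) {
  stopifnot(inherits(result, "dea_result"))
  utils::write.csv(result, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(attr(result, "model"), paste0(prefix, "_model.json"),
                       auto_unbox = TRUE)
  invisible(prefix)
}
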