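# RUV factor estimators on log2 expression matrices.
#
# All three estimators work on the linear model
#   log2(Y) = W alpha + X beta + eps,
# with W (m x K) the unwanted factors and alpha (K x G) their loadings. They
# differ in what anchors the estimation: negative control genes (RUV2),
# control genes plus design residuals (RUV4), or control genes plus negative
# control samples, i.e. technical replicates (RUVIII). "Factor analysis" is
# truncated SVD throughout, as in the ruv-package lineage; no rotation.

new_ruv_fit <- function(W, alpha, K, method, ctl, design_used = NULL, M = NULL) {
  if (any(!is.finite(W))) stopf("estimated W contains non-finite entries")
  structure(list(W = W, alpha = alpha, K = K, method = method, ctl = ctl,
                 design_used = design_used, M = M),
            class = "ruv_fit")
}

#' @exportS3Method base::print
print.ruv_fit <- function(x, ...) {
  cat(sprintf("ruv_fit: %s, K = %d, %d samples x %d genes (%d controls)\n",
              x$method, x$K, nrow(x$W), ncol(x$alpha), sum(x$ctl)))
  invisible(x)
}

# Make SVD output reproducible across platforms: for each factor, the
# largest-|loading| entry of its alpha row is made positive.
fix_signs <- function(W, alpha) {
  for (k in seq_len(nrow(alpha))) {
    j <- which.max(abs(alpha[k, ]))
    if (alpha[k, j] < 0) {
      alpha[k, ] <- -alpha[k, ]
      W[, k] <- -W[, k]
    }
  }
  list(W = W, alpha = alpha)
}

as_ctl_mask <- function(ctl, G) {
  if (is.logical(ctl)) {
    if (length(ctl) != G) stopf("logical ctl mask must have length %d", G)
    return(ctl)
  }
  mask <- rep(FALSE, G)
  mask[ctl] <- TRUE
  mask
}

#' RUV2: factor analysis on negative control genes
#'
#' Estimates K unwanted factors by truncated SVD of the column-centered
#' log2 expression of the negative control genes, then regresses the full
#' matrix on the factors to obtain loadings for every gene. Control genes are
#' assumed unaffected by the factor of interest, so by default no design is
#' residualized out; pass \code{design} to estimate the factors conditional
#' on a design matrix instead.
#'
#' @param Yl numeric matrix, m samples x G genes, log2 scale.
#' @param ctl negative-control genes: logical mask of length G, or
#'   integer/character indices.
#' @param k number of unwanted factors.
#' @param design optional m x Q matrix; when given, control genes are
#'   residualized on it (instead of the intercept) before the SVD.
#' @return A \code{ruv_fit} with \code{W} (m x k, left singular vectors
#'   scaled by singular values), \code{alpha} (k x G, OLS of \code{Yl} on
#'   \code{W}). Factor signs are fixed so each loading row's largest-|value|
#'   entry is positive.
#' @export
ruv2 <- function(Yl, ctl, k, design = NULL) {
  Yl <- as.matrix(Yl)
  m <- nrow(Yl)
  ctl <- as_ctl_mask(ctl, ncol(Yl))
  if (k < 1) stopf("k must be >= 1")
  if (k > min(m - 1L, sum(ctl)))
    stopf("k = %d exceeds the available rank: min(m - 1 = %d, controls = %d)",
          k, m - 1L, sum(ctl))
  Yc <- Yl[, ctl, drop = FALSE]
  Yc <- if (is.null(design)) scale(Yc, center = TRUE, scale = FALSE)
        else residual_op(cbind(design)) %*% Yc
  sv <- svd(Yc)
  if (sv$d[k] <= 1e-12 * max(sv$d, 1e-300))
    stopf("control-gene matrix has rank < k after centering (degenerate input)")
  W <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  alpha <- pinv(crossprod(W), warn = FALSE) %*% t(W) %*% Yl
  fx <- fix_signs(W, alpha)
  rownames(fx$W) <- rownames(Yl)
  colnames(fx$alpha) <- colnames(Yl)
  new_ruv_fit(fx$W, fx$alpha, k, "RUV2", ctl,
              design_used = if (!is.null(design)) "design" else "intercept")
}

#' RUV4: control genes plus design residuals
#'
#' Estimates loadings from the SVD of the residuals of \code{Yl} on the
#' design \code{X} (so the factor of interest cannot leak into them), then
#' recovers the factors from the column-centered control genes:
#' \code{W = Yc[, ctl] alpha_c' (alpha_c alpha_c')^-1} (centering plays the
#' role of the intercept-removal preprocessing step in the classical
#' four-step procedure; gene means otherwise leak into W). Assumes the
#' unwanted factors are not orthogonal complements of the design.
#'
#' @inheritParams ruv2
#' @param X design matrix m x Q, full column rank (the factor(s) of interest,
#'   including any intercept).
#' @return A \code{ruv_fit}; see \code{\link{ruv2}} for the slot conventions.
#' @export
ruv4 <- function(Yl, X, ctl, k) {
  Yl <- as.matrix(Yl)
  X <- cbind(X)
  m <- nrow(Yl)
  ctl <- as_ctl_mask(ctl, ncol(Yl))
  if (qr(X)$rank < ncol(X)) stopf("design X is not of full column rank")
  if (k < 1 || k > m - ncol(X))
    stopf("k must be in 1..(m - ncol(X)) = 1..%d", m - ncol(X))
  R <- residual_op(X) %*% Yl
  sv <- svd(R)
  if (sv$d[k] <= 1e-12 * max(sv$d, 1e-300) ||
      max(sv$d) <= 1e-10 * sqrt(sum(Yl^2) + 1e-300))
    stopf("residual matrix has rank < k (no unwanted variation left to estimate)")
  alpha <- diag(sv$d[seq_len(k)], k) %*% t(sv$v[, seq_len(k), drop = FALSE])
  ac <- alpha[, ctl, drop = FALSE]
  aat <- tcrossprod(ac)
  if (rcond(aat) < 1e-12)
    warnf("alpha restricted to the control genes is near-singular; %s",
          "consider a larger control set or smaller k (using pseudo-inverse)")
  Yc <- scale(Yl[, ctl, drop = FALSE], center = TRUE, scale = FALSE)
  W <- Yc %*% t(ac) %*% pinv(aat, warn = FALSE)
  fx <- fix_signs(W, alpha)
  rownames(fx$W) <- rownames(Yl)
  colnames(fx$alpha) <- colnames(Yl)
  new_ruv_fit(fx$W, fx$alpha, k, "RUV4", ctl, design_used = "X")
}

#' Replicate-group membership matrix
#'
#' Encodes negative control samples (technical replicates) as a binary
#' m x r matrix M with one column per replicate group and exactly one 1 per
#' row, as consumed by \code{\link{ruviii}}.
#'
#' @param labels per-sample replicate-group identifiers (one per sample).
#' @return Binary matrix with \code{rownames = names(labels)} when present
#'   and columns named by group.
#' @export
make_replicate_matrix <- function(labels) {
  f <- factor(labels)
  M <- matrix(0, length(f), nlevels(f),
              dimnames = list(names(labels), levels(f)))
  M[cbind(seq_along(f), as.integer(f))] <- 1
  M
}

#' RUVIII: control genes plus negative control samples
#'
#' Estimates loadings from the SVD of the replicate residuals
#' \code{(I - M (M'M)^-1 M') Yl} -- variation between technical replicates of
#' the same sample, which is unwanted by assumption -- then recovers per-sample
#' factors from the control genes as in RUV4, and returns the normalized
#' matrix \code{Ystar = Yl - W alpha}.
#'
#' @inheritParams ruv2
#' @param M replicate membership matrix from
#'   \code{\link{make_replicate_matrix}}; at least one group must contain two
#'   or more samples.
#' @return list with components \code{fit} (a \code{ruv_fit}) and
#'   \code{Ystar} (m x G normalized log2 matrix).
#' @export
ruviii <- function(Yl, M, ctl, k) {
  Yl <- as.matrix(Yl)
  m <- nrow(Yl)
  ctl <- as_ctl_mask(ctl, ncol(Yl))
  M <- as.matrix(M)
  if (nrow(M) != m) stopf("M has %d rows but Yl has %d samples", nrow(M), m)
  r <- ncol(M)
  if (max(colSums(M)) < 2)
    stopf("no negative control samples: every replicate group is a singleton")
  if (k < 1 || k > m - r)
    stopf("k must be in 1..(m - r) = 1..%d", m - r)
  R <- residual_op(M) %*% Yl
  sv <- svd(R)
  if (sv$d[k] <= 1e-12 * max(sv$d, 1e-300))
    stopf("replicate residuals have rank < k")
  alpha <- diag(sv$d[seq_len(k)], k) %*% t(sv$v[, seq_len(k), drop = FALSE])
  ac <- alpha[, ctl, drop = FALSE]
  aat <- tcrossprod(ac)
  if (rcond(aat) < 1e-12)
    warnf("alpha restricted to the control genes is near-singular; %s",
          "consider a larger control set or smaller k (using pseudo-inverse)")
  W <- Yl[, ctl, drop = FALSE] %*% t(ac) %*% pinv(aat, warn = FALSE)
  fx <- fix_signs(W, alpha)
  rownames(fx$W) <- rownames(Yl)
  colnames(fx$alpha) <- colnames(Yl)
  fit <- new_ruv_fit(fx$W, fx$alpha, k, "RUVIII", ctl, M = M)
  list(fit = fit, Ystar = Yl - fx$W %*% fx$alpha)
}

#' Regress estimated unwanted factors out of a log2 matrix
#'
#' Produces the normalized matrix \code{Ystar}. With \code{refit_alpha = TRUE}
#' (default) the loadings are re-estimated by projection, so
#' \code{Ystar = (I - W (W'W)^-1 W') Yl} is exactly orthogonal to W;
#' otherwise the fit's stored loadings are used, \code{Ystar = Yl - W alpha}.
#' The normalized matrix is intended for diagnostics (RLE, PCA, silhouettes);
#' running the DEA on it risks removing biological signal -- pass W as
#' covariates to \code{\link{fit_dea}} instead.
#'
#' @inheritParams ruv2
#' @param fit a \code{ruv_fit} whose W rows align with the rows of \code{Yl}.
#' @param refit_alpha logical; see Details.
#' @return m x G normalized matrix.
#' @export
normalize_out <- function(Yl, fit, refit_alpha = TRUE) {
  Yl <- as.matrix(Yl)
  stopifnot(inherits(fit, "ruv_fit"))
  if (nrow(fit$W) != nrow(Yl))
    stopf("fit$W has %d rows but Yl has %d", nrow(fit$W), nrow(Yl))
  if (refit_alpha) {
    residual_op(fit$W) %*% Yl
  } else {
    if (ncol(fit$alpha) != ncol(Yl))
      stopf("fit$alpha has %d genes but Yl has %d", ncol(fit$alpha), ncol(Yl))
    Yl - fit$W %*% fit$alpha
  }
}
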