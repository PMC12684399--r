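# Internal numerical helpers.

# Moore-Penrose pseudo-inverse via SVD with a relative tolerance; warns when
# the matrix is treated as rank-deficient so callers see degraded solves.
pinv <- function(A, rtol = 1e-10, warn = TRUE) {
  sv <- svd(A)
  keep <- sv$d > rtol * max(sv$d, 0)
  if (!all(keep) && warn) {
    warning(sprintf(
      "matrix is numerically rank-deficient (rank %d of %d); using pseudo-inverse",
      sum(keep), length(keep)
    ), call. = FALSE)
  }
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, keep, drop = FALSE] %*%
    ((1 / sv$d[keep]) * t(sv$u[, keep, drop = FALSE]))
}

geometric_mean <- function(x) exp(mean(log(x)))

# Hat-matrix residual maker I - Z (Z'Z)^- Z'.
residual_op <- function(Z) {
  diag(nrow(Z)) - Z %*% pinv(crossprod(Z), warn = FALSE) %*% t(Z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
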