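test_that("RUV2 recovers a planted additive batch shift exactly", {
  set.seed(11)
  m <- 8; G <- 40
  batch <- rep(c(0, 1), each = 4)
  delta <- rnorm(G, 0, 1)
  base <- matrix(rnorm(G), m, G, byrow = TRUE)
  Yl <- base + outer(batch, delta)
  fit <- ruv2(Yl, ctl = rep(TRUE, G), k = 1)
  expect_equal(abs(cor(fit$W[, 1], batch)), 1, tolerance = 1e-6)
  # exact eigendecomposition oracle on the centered controls
  Yc <- scale(Yl, center = TRUE, scale = FALSE)
  ev <- eigen(tcrossprod(Yc), symmetric = TRUE)$vectors[, 1]
  expect_lt(principal_angle(fit$W, cbind(ev)), 1e-6)
})

test_that("RUV2 flags degenerate inputs and fixes factor signs", {
  Yl <- matrix(1, 6, 12)
  expect_error(ruv2(Yl, rep(TRUE, 12), k = 1), "rank|degenerate")
  set.seed(2)
  Yl <- matrix(rnorm(6 * 12), 6, 12)
  expect_error(ruv2(Yl, rep(TRUE, 12), k = 6), "exceeds")
  fit <- ruv2(Yl, rep(TRUE, 12), k = 2)
  # sign convention: largest-|loading| entry of each alpha row is positive
  for (k in 1:2) expect_gt(fit$alpha[k, which.max(abs(fit$alpha[k, ]))], 0)
  # flipping a factor and its loadings leaves the fitted W alpha unchanged
  expect_equal((-fit$W[, 1]) %o% (-fit$alpha[1, ]),
               fit$W[, 1] %o% fit$alpha[1, ])
})

test_that("RUV4 with all controls and intercept design matches RUV2's subspace", {
  set.seed(21)
  Yl <- matrix(rnorm(10 * 50), 10, 50)
  k <- 3
  f2 <- ruv2(Yl, rep(TRUE, 50), k)
  f4 <- ruv4(Yl, X = matrix(1, 10, 1), ctl = rep(TRUE, 50), k = k)
  expect_lt(principal_angle(f2$W, f4$W), 1e-6)
})

test_that("RUV4 recovers a planted factor orthogonal to the design", {
  set.seed(31)
  m <- 20; G <- 100
  X <- cbind(1, rep(0:1, each = 10))
  w_star <- residual_op_test <- rnorm(m)
  w_star <- w_star - X %*% solve(crossprod(X), crossprod(X, w_star))  # orthogonalize
  alpha_star <- rnorm(G, 0, 2)
  Yl <- X %*% rbind(rnorm(G), rnorm(G)) + w_star %*% t(alpha_star) +
    matrix(rnorm(m * G, 0, 0.05), m, G)
  fit <- ruv4(Yl, X, ctl = rep(TRUE, G), k = 1)
  expect_gt(abs(cor(fit$W[, 1], w_star)), 0.99)
  # degenerate: no residual variation left
  Y0 <- X %*% rbind(rnorm(G), rnorm(G))
  expect_error(ruv4(Y0, X, rep(TRUE, G), k = 1), "rank")
  expect_error(ruv4(Yl, cbind(X, X[, 1]), rep(TRUE, G), k = 1), "full column rank")
})

test_that("replicate membership matrices encode the groups", {
  M <- make_replicate_matrix(c("a", "a", "b"))
  expect_equal(unname(M), rbind(c(1, 0), c(1, 0), c(0, 1)))
  expect_equal(unname(make_replicate_matrix(c("x", "y", "z"))), diag(3))
  labs <- sample(letters[1:3], 20, replace = TRUE)
  expect_equal(unname(colSums(make_replicate_matrix(labs))),
               unname(as.vector(table(labs))))
})

test_that("RUVIII equalizes technical replicates differing by a batch vector", {
  set.seed(41)
  G <- 30
  subj <- matrix(rnorm(3 * G), 3, G)       # 3 subjects
  delta <- rnorm(G, 0, 1)                  # additive gene-wise batch shift
  Yl <- rbind(subj, sweep(subj, 2, delta, `+`))  # replicate 2 shifted
  M <- make_replicate_matrix(rep(1:3, 2))
  out <- ruviii(Yl, M, ctl = rep(TRUE, G), k = 1)
  for (j in 1:3)
    expect_lt(max(abs(out$Ystar[j, ] - out$Ystar[j + 3, ])), 1e-8)
})

test_that("RUVIII requires real replication and a feasible k", {
  Yl <- matrix(rnorm(5 * 20), 5, 20)
  expect_error(ruviii(Yl, diag(5), rep(TRUE, 20), 1), "no negative control samples")
  M <- make_replicate_matrix(c(1, 1, 2, 2, 3))
  expect_error(ruviii(Yl, M, rep(TRUE, 20), 3), "k must be in")
})

test_that("W subspaces match a brute-force eigendecomposition oracle (<= 12x60)", {
  set.seed(51)
  m <- 12; G <- 60; k <- 3
  Yl <- matrix(rnorm(m * G), m, G) +
    matrix(rnorm(m), m, 1) %*% matrix(rnorm(G), 1, G)
  ctl <- rep(TRUE, G)
  # RUV2 oracle: top-k eigenvectors of Yc Yc'
  Yc <- scale(Yl, center = TRUE, scale = FALSE)
  W2 <- eigen(tcrossprod(Yc), symmetric = TRUE)$vectors[, 1:k]
  expect_lt(principal_angle(ruv2(Yl, ctl, k)$W, W2), 1e-6)
  # RUV4 oracle: alpha from eigenvectors of (RY)'(RY), W by projection
  X <- cbind(1, rep(0:1, 6))
  R <- diag(m) - X %*% solve(crossprod(X), t(X))
  RY <- R %*% Yl
  A <- t(eigen(crossprod(RY), symmetric = TRUE)$vectors[, 1:k])
  Ycen <- scale(Yl, center = TRUE, scale = FALSE)
  W4o <- Ycen %*% t(A) %*% solve(A %*% t(A))
  expect_lt(principal_angle(ruv4(Yl, X, ctl, k)$W, W4o), 1e-6)
  # RUVIII oracle: same construction with the replicate operator
  M <- make_replicate_matrix(rep(1:6, each = 2))
  RM <- diag(m) - M %*% solve(crossprod(M), t(M))
  RY <- RM %*% Yl
  A <- t(eigen(crossprod(RY), symmetric = TRUE)$vectors[, 1:k])
  W3o <- Yl %*% t(A) %*% solve(A %*% t(A))
  expect_lt(principal_angle(ruviii(Yl, M, ctl, k)$fit$W, W3o), 1e-6)
})

test_that("normalizing out W is an orthogonal, idempotent projection", {
  set.seed(61)
  Yl <- matrix(rnorm(10 * 40), 10, 40)
  fit <- ruv2(Yl, rep(TRUE, 40), k = 2)
  Ystar <- normalize_out(Yl, fit, refit_alpha = TRUE)
  expect_lt(max(abs(crossprod(fit$W, Ystar))), 1e-10)
  expect_equal(normalize_out(Ystar, fit, refit_alpha = TRUE), Ystar,
               tolerance = 1e-12)
  # k = m - 1 on centered data over-corrects: rows collapse together
  Yc <- scale(Yl, center = TRUE, scale = FALSE)
  fit_full <- ruv2(Yc, rep(TRUE, 40), k = 9)
  Yover <- normalize_out(Yc, fit_full, refit_alpha = TRUE)
  expect_lt(max(apply(Yover, 2, function(x) diff(range(x)))), 1e-8)
})
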