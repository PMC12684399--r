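# Shared fixtures and independent brute-force oracles.

# Small simulated dataset for pipeline-level tests.
quick_sim <- function(seed = 1, n_genes = 300, n_subjects = 8, n_batches = 2,
                      cells_per_sample_mean = 30, ...) {
  simulate_dataset(sim_config(
    n_subjects = n_subjects, n_batches = n_batches, n_genes = n_genes,
    cells_per_sample_mean = cells_per_sample_mean, seed = seed, ...))
}

# Hand-built 3-cell dataset: cells 1,2 in (s1, tA), cell 3 in (s1, tB).
toy_dataset <- function() {
  counts <- matrix(c(1, 2, 0,
                     0, 1, 1,
                     3, 0, 2), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("c", 1:3), paste0("g", 1:3)))
  meta <- data.frame(sample = c("s1", "s1", "s1"),
                     celltype = c("tA", "tA", "tB"))
  cell_dataset(counts, meta)
}

# Brute-force silhouette widths from first principles.
silhouette_brute <- function(X, labels) {
  X <- as.matrix(X)
  f <- as.character(labels)
  n <- nrow(X)
  d <- as.matrix(dist(X))
  vapply(seq_len(n), function(i) {
    own <- setdiff(which(f == f[i]), i)
    if (length(own) == 0) return(0)  # singleton cluster convention
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(f), f[i]),
                    function(g) mean(d[i, f == g]), 0))
    (b - a) / max(a, b)
  }, 0)
}

# Brute-force Benjamini-Hochberg: largest k with p_(k) <= k/m * q.
bh_brute <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * q)
  if (length(k) == 0) return(integer(0))
  sort(o[seq_len(max(k))])
}

# Largest principal angle (radians) between the column spaces of A and B.
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s))))
}

# Cramer's V from a brute-force contingency table.
cramers_v <- function(x, y) {
  tab <- table(x, y)
  chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  sqrt(unname(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
}

# Shared log2 UQ pseudobulk for a simulated dataset.
pb_of <- function(sim) log2p1(uq_normalize(pseudobulk(sim$dataset)))

# Worked-example fixture: six single-cell samples, two biological covariates
# (factor of interest x cell type, two levels each, so B = 4), one technical
# covariate with two batches (L = 2). Subgroup 1 (foi = f1, celltype = A)
# holds 7 cells from 3 samples, 4 of them in batch 1.
fig_fixture <- function(n_genes = 10) {
  meta <- data.frame(
    sample   = c("s1", "s1", "s2", "s2", "s3", "s3", "s3",   # subgroup 1
                 "s1", "s2", "s4", "s4", "s5", "s5", "s6", "s6"),
    foi      = c(rep("f1", 7), "f1", "f1", rep("f2", 6)),
    celltype = c(rep("A", 7), "B", "B", "A", "B", "A", "B", "A", "B"),
    batch    = c("b1", "b1", "b1", "b1", "b2", "b2", "b2",
                 "b1", "b1", "b2", "b2", "b2", "b2", "b2", "b2"))
  set.seed(99)
  counts <- matrix(rpois(nrow(meta) * n_genes, 5), nrow(meta), n_genes)
  cell_dataset(counts, meta)
}
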