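test_that("the schematic worked example stratifies as described", {
  ds <- fig_fixture()
  cfg <- pbps_config(c("foi", "celltype"), "batch", n_pseudosamples = 3,
                     seed = 1)
  grp <- define_groups(ds, cfg)
  expect_equal(nlevels(grp$bio), 4L)              # B = 2 x 2
  c1 <- grp$cbar[["f1|A"]]
  expect_equal(c1, 7 / 3)                         # 7 cells from 3 samples
  expect_equal(round(c1, 1), 2.3)                 # displayed value
  expect_equal(sum(grp$bio == "f1|A" & grp$uv == "b1"), 4L)
})

test_that("pseudosample counts follow I x (non-empty strata)", {
  ds <- fig_fixture()
  cfg <- pbps_config(c("foi", "celltype"), "batch", n_pseudosamples = 3,
                     seed = 2)
  res <- suppressWarnings(generate_pbps(ds, cfg))
  n_strata <- sum(table(define_groups(ds, cfg)$bio,
                        define_groups(ds, cfg)$uv) > 0)
  expect_equal(sum(!res$origin_mask), 3L * n_strata)
  # every cell in its own sample and subgroup: c_bar = 1 everywhere
  solo <- cell_dataset(matrix(rpois(40, 3), 4, 10),
                       data.frame(sample = paste0("s", 1:4),
                                  celltype = paste0("t", 1:4),
                                  batch = "b1"))
  cfgs <- pbps_config("celltype", "batch", n_pseudosamples = 2, seed = 1)
  expect_true(all(define_groups(solo, cfgs)$cbar == 1))
})

test_that("each pseudosample is the exact integer sum of its sampled cells", {
  ds <- fig_fixture(n_genes = 15)
  cfg <- pbps_config(c("foi", "celltype"), "batch", n_pseudosamples = 4,
                     seed = 3)
  res <- suppressWarnings(generate_pbps(ds, cfg))
  counts <- res$augmented$counts[!res$origin_mask, , drop = FALSE]
  for (i in seq_len(nrow(counts))) {
    cells <- strsplit(res$pbps_meta$cells[i], ",")[[1]]
    manual <- colSums(as.matrix(ds$counts[cells, , drop = FALSE]))
    expect_identical(unname(counts[i, ]), unname(manual))
  }
  # original rows are untouched
  orig <- pseudobulk(ds)
  expect_identical(res$augmented$counts[res$origin_mask, ], orig$counts)
})

test_that("a singleton stratum yields identical pseudosamples", {
  # one cell per sample so c_bar = 1; the b1 stratum holds a single cell
  meta1 <- data.frame(sample = c("x1", "x2", "x3"),
                      foi = "f2", celltype = "A",
                      batch = c("b1", "b2", "b2"))
  set.seed(6)
  ds1 <- cell_dataset(matrix(rpois(30, 4), 3, 10), meta1)
  cfg1 <- pbps_config(c("foi", "celltype"), "batch", n_pseudosamples = 3,
                      seed = 5)
  res1 <- generate_pbps(ds1, cfg1)
  expect_true(all(define_groups(ds1, cfg1)$cbar == 1))
  pb1 <- res1$augmented$counts[!res1$origin_mask, , drop = FALSE]
  b1_rows <- pb1[res1$pbps_meta$l == "b1", , drop = FALSE]
  expect_equal(nrow(b1_rows), 3L)
  single <- as.numeric(ds1$counts[1, ])
  for (i in seq_len(nrow(b1_rows)))
    expect_equal(unname(b1_rows[i, ]), single)
})

test_that("pseudosample generation is seed-deterministic", {
  ds <- fig_fixture()
  cfg <- pbps_config(c("foi", "celltype"), "batch", n_pseudosamples = 3,
                     seed = 11)
  a <- suppressWarnings(generate_pbps(ds, cfg))
  b <- suppressWarnings(generate_pbps(ds, cfg))
  expect_identical(a$augmented$counts, b$augmented$counts)
  expect_identical(a$pbps_meta$cells, b$pbps_meta$cells)
})

test_that("the replicate structure groups pseudosamples by biology", {
  ds <- fig_fixture()
  cfg <- pbps_config(c("foi", "celltype"), "batch", n_pseudosamples = 3,
                     seed = 7)
  res <- suppressWarnings(generate_pbps(ds, cfg))
  M <- pbps_replicate_structure(res)
  S <- sum(res$origin_mask)
  n_bio_with_ps <- length(unique(res$pbps_meta$b))
  expect_equal(ncol(M), S + n_bio_with_ps)
  expect_true(all(rowSums(M) == 1))
  # restricted to originals, the structure collapses to the identity
  # (columns are named by group; original groups are the row ids)
  M_orig <- M[res$origin_mask, , drop = FALSE]
  expect_equal(unname(M_orig[, rownames(M_orig)]), diag(S))
})

test_that("ruviii_pbps needs celltype among the biological covariates", {
  ds <- fig_fixture()
  cfg <- pbps_config("foi", "batch", n_pseudosamples = 2, seed = 1)
  expect_error(ruviii_pbps(ds, cfg), "biological covariates")
})

test_that("PBPS factors associate with batch on a strongly batched dataset", {
  sim <- quick_sim(seed = 23, n_genes = 300, n_batches = 4, n_subjects = 12,
                   batch_effect_sd = 1.0, scenario = "confounded",
                   cells_per_sample_mean = 60)
  cfg <- pbps_config(c("treatment", "ethnicity", "celltype"), "batch",
                     n_pseudosamples = 5, seed = 23)
  W <- suppressWarnings(ruviii_pbps(sim$dataset, cfg, k = 3))
  pb <- pb_of(sim)
  for (t in names(W)) {
    rows <- rownames(W[[t]])
    batch <- pb$sample_meta[rows, "batch"]
    wa <- w_association(W[[t]], batch)
    expect_true(all(wa$per_factor$kw_p < 0.05))
  }
})

test_that("same-biology pseudosamples are exchangeable without batch effects", {
  # with no batch effect, library sizes of pseudosamples of one biological
  # subgroup must be indistinguishable across batches
  ok <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    sim <- quick_sim(seed = 300 + s, n_genes = 100, n_batches = 2,
                     batch_effect_sd = 0, sample_random_effect_sd = 0,
                     de_fraction = 0, cells_per_sample_mean = 40)
    cfg <- pbps_config(c("treatment", "celltype"), "batch",
                       n_pseudosamples = 8, seed = s)
    res <- suppressWarnings(generate_pbps(sim$dataset, cfg))
    lib <- rowSums(res$augmented$counts[!res$origin_mask, , drop = FALSE])
    b <- res$pbps_meta$b[1]
    sel <- res$pbps_meta$b == b
    pv <- wilcox.test(lib[sel][res$pbps_meta$l[sel] == "batch1"],
                      lib[sel][res$pbps_meta$l[sel] == "batch2"],
                      exact = FALSE)$p.value
    if (pv > 0.01) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
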