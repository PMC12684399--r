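test_that("identical configurations give bit-identical datasets", {
  cfg <- sim_config(n_subjects = 8, n_batches = 2, n_genes = 50,
                    cells_per_sample_mean = 20, scenario = "confounded",
                    n_ctl_genes = 5, seed = 123)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.matrix(a$dataset$counts), as.matrix(b$dataset$counts))
  expect_identical(a$truth$assignment, b$truth$assignment)
  expect_identical(a$truth$de_genes, b$truth$de_genes)
})

test_that("without planted structure, batches differ only by sampling error", {
  sim <- quick_sim(seed = 17, n_genes = 400, n_subjects = 12,
                   cells_per_sample_mean = 60,
                   batch_effect_sd = 0, sample_random_effect_sd = 0,
                   de_fraction = 0)
  ds <- sim$dataset
  b <- ds$cell_meta$batch
  # per-gene two-sample t between batches: ~5% significant at alpha 0.05
  m1 <- as.matrix(ds$counts[b == "batch1", ])
  m2 <- as.matrix(ds$counts[b == "batch2", ])
  keep <- colSums(m1) + colSums(m2) > 20
  pv <- vapply(which(keep), function(g) t.test(m1[, g], m2[, g])$p.value, 0)
  expect_lt(mean(pv < 0.05), 0.12)
})

test_that("a strong batch effect separates batches in pseudobulk PC space", {
  sim <- quick_sim(seed = 19, n_genes = 300, batch_effect_sd = 1.0,
                   de_fraction = 0)
  pb <- pb_of(sim)
  res <- asw(pb$logmat, pb$sample_meta$batch, n_pcs = 10)
  expect_gt(res$asw, 0.3)
  # verify against the brute-force silhouette oracle on the same PCs
  Yc <- scale(pb$logmat, center = TRUE, scale = FALSE)
  pcs <- prcomp(Yc, rank. = res$n_pcs)$x
  expect_equal(unname(res$widths),
               silhouette_brute(pcs, pb$sample_meta$batch),
               tolerance = 1e-10)
})

test_that("balanced assignment stratifies treatments within every batch", {
  meta <- data.frame(sample = sprintf("s%02d", 1:16),
                     batch = rep(paste0("b", 1:4), each = 4))
  trt <- assign_mock_treatment(meta, "balanced", seed = 4)
  tab <- table(meta$batch, trt)
  expect_true(all(tab == 2))
  small <- data.frame(sample = c("s1", "s2", "s3"), batch = c("b1", "b1", "b2"))
  expect_error(assign_mock_treatment(small, "balanced", seed = 1), "fewer than 2")
})

test_that("confounded assignment ties treatment to batch with given strength", {
  meta <- data.frame(sample = sprintf("s%02d", 1:8),
                     batch = rep(c("b1", "b2"), each = 4))
  trt <- assign_mock_treatment(meta, "confounded", strength = 1, seed = 2)
  expect_true(all(trt[meta$batch == "b1"] == "A"))
  expect_true(all(trt[meta$batch == "b2"] == "B"))
  # strength 0.8, 20 samples: Cramer's V in (0.5, 1.0)
  meta20 <- data.frame(sample = sprintf("s%02d", 1:20),
                       batch = rep(paste0("b", 1:4), each = 5))
  v <- cramers_v(assign_mock_treatment(meta20, "confounded",
                                       strength = 0.8, seed = 3),
                 meta20$batch)
  expect_gt(v, 0.5)
  expect_lt(v, 1.0)
})

test_that("spiking marks the stated fraction of genes and respects controls", {
  cfg <- sim_config(n_subjects = 8, n_batches = 2, n_genes = 1000,
                    cells_per_sample_mean = 15, de_fraction = 0.10,
                    n_ctl_genes = 100, seed = 31)
  sim <- simulate_dataset(cfg)
  expect_length(sim$truth$de_genes[[1]], 100L)  # 10% of genes
  expect_length(intersect(sim$truth$de_genes[[1]], sim$truth$ctl_genes), 0L)
  # explicit request to spike a control gene errors
  expect_error(
    spike_de(sim$dataset, sim$truth, cfg, genes = sim$truth$ctl_genes[1]),
    "negative-control")
})

test_that("a null spike leaves counts unchanged", {
  cfg <- sim_config(n_subjects = 8, n_batches = 2, n_genes = 50,
                    cells_per_sample_mean = 20, de_fraction = 0,
                    seed = 37)
  sim <- simulate_dataset(cfg)
  cfg0 <- cfg; cfg0$de_logfc <- 0; cfg0$de_fraction <- 0.1
  sp <- spike_de(sim$dataset, sim$truth, cfg0, seed = 1)
  expect_identical(as.matrix(sp$dataset$counts), as.matrix(sim$dataset$counts))
})

test_that("the spiked pseudobulk fold change matches the requested magnitude", {
  # one highly expressed gene, de_logfc = 1: observed log2 B/A ratio near +-1
  cfg <- sim_config(n_subjects = 8, n_batches = 2, n_genes = 50,
                    cells_per_sample_mean = 60,
                    baseline_logmean = c(mu = 4, sigma = 0.2),
                    batch_effect_sd = 0, sample_random_effect_sd = 0,
                    nb_dispersion = 0.05, de_fraction = 0, seed = 41)
  sim <- simulate_dataset(cfg)
  cfg$de_fraction <- 0.02  # one gene
  sp <- spike_de(sim$dataset, sim$truth, cfg, seed = 9)
  g <- sp$truth$de_genes[[1]]
  trt <- sp$dataset$cell_meta$treatment
  ratio <- log2(sum(sp$dataset$counts[trt == "B", g]) /
                  sum(sp$dataset$counts[trt == "A", g]))
  expect_lt(abs(abs(ratio) - 1), 0.2)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 5), "n_genes")
  expect_error(sim_config(n_subjects = 4, n_batches = 4), "fewer than 2 samples")
  expect_error(sim_config(de_fraction = 1), "de_fraction")
  expect_error(sim_config(batch_effect_sd = -1), "batch_effect_sd")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
})

test_that("truth serializes to JSON", {
  sim <- quick_sim(seed = 2, n_genes = 40, de_fraction = 0.1)
  p <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$scenario, sim$truth$scenario)
  expect_equal(unlist(back$de_genes[[1]]), unname(sim$truth$de_genes[[1]]))
})
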