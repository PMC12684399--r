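# Synthetic multi-sample, multi-batch single-cell count generator.
#
# Counts are negative binomial with a log2-linear mean:
#   log2 mu_cg = base_g + celltype_{t(c),g} + batch_{l(c),g}
#                + batchXcelltype_{l(c),t(c),g} + sample_{n(c),g}
# The per-sample, per-gene random effect induces within-sample correlation
# (cells from one sample share it), which is the structure that makes
# pseudobulk samples from the same single-cell sample correlated.

#' Simulation configuration
#'
#' Parameters of the synthetic single-cell generator. Effect spreads are
#' standard deviations on the log2 scale of the negative-binomial mean.
#'
#' @param n_subjects number of subjects.
#' @param n_samples_per_subject technical replicates per subject (replicates
#'   of one subject are spread over different batches).
#' @param n_celltypes,n_batches,n_genes dimensions T, L, G.
#' @param cells_per_sample_mean Poisson mean of cells per single-cell sample.
#' @param baseline_logmean length-2 vector (mu, sigma): per-gene baseline
#'   log2 mean expression per cell is N(mu, sigma).
#' @param celltype_effect_sd per-gene spread of cell-type effects.
#' @param batch_effect_sd per-gene, per-batch spread of batch effects (the
#'   planted unwanted variation).
#' @param batch_celltype_sd spread of batch-by-cell-type interaction effects
#'   (gene loadings of the categorical batch effect differ by cell type);
#'   0 by default.
#' @param celltype_uv_factor_sd loading spread of a continuous unwanted
#'   factor scored independently per (sample, cell type): each pseudobulk
#'   sample (n, t) gets a score u ~ N(0, 1) and gene g is shifted by
#'   u * lambda_g with lambda_g ~ N(0, sd). This plants cell-type-specific
#'   unwanted variation that per-sample (trail T3) estimation cannot see,
#'   e.g. cell-quality differences between cell types of one sample. 0 by
#'   default.
#' @param sample_random_effect_sd per-sample, per-gene log2 noise inducing
#'   within-sample correlation.
#' @param nb_dispersion negative-binomial dispersion (\code{size} =
#'   1/dispersion).
#' @param de_fraction fraction of genes spiked as differentially expressed
#'   between the two mock treatments.
#' @param de_logfc log2 fold-change magnitude of spiked genes (sign split
#'   50/50 per gene).
#' @param interaction_logfc extra log2 fold change applied to spiked genes in
#'   treatment-B cells of the second ethnicity group under the
#'   \code{confounded_interaction} scenario (the treatment effect then truly
#'   interacts with ethnicity).
#' @param n_ctl_genes number of genes registered as negative controls; these
#'   are never spiked.
#' @param scenario treatment-assignment scenario: \code{"balanced"},
#'   \code{"confounded"} or \code{"confounded_interaction"}.
#' @param confound_strength under the confounded scenarios, the fraction of
#'   treatment-A samples placed in the first half of the batches.
#' @param seed RNG seed; identical configurations yield identical datasets.
#' @return A \code{sim_config} list, validated.
#' @export
sim_config <- function(n_subjects = 16, n_samples_per_subject = 1,
                       n_celltypes = 2, n_batches = 4, n_genes = 2000,
                       cells_per_sample_mean = 100,
                       baseline_logmean = c(mu = -1, sigma = 2),
                       celltype_effect_sd = 0.5,
                       batch_effect_sd = 0.5,
                       batch_celltype_sd = 0,
                       celltype_uv_factor_sd = 0,
                       sample_random_effect_sd = 0.15,
                       nb_dispersion = 0.3,
                       de_fraction = 0.10, de_logfc = 1,
                       interaction_logfc = 0.5,
                       n_ctl_genes = 0,
                       scenario = c("balanced", "confounded",
                                    "confounded_interaction"),
                       confound_strength = 0.8,
                       seed = 1) {
  scenario <- match.arg(scenario)
  cfg <- list(n_subjects = n_subjects,
              n_samples_per_subject = n_samples_per_subject,
              n_celltypes = n_celltypes, n_batches = n_batches,
              n_genes = n_genes,
              cells_per_sample_mean = cells_per_sample_mean,
              baseline_logmean = baseline_logmean,
              celltype_effect_sd = celltype_effect_sd,
              batch_effect_sd = batch_effect_sd,
              batch_celltype_sd = batch_celltype_sd,
              celltype_uv_factor_sd = celltype_uv_factor_sd,
              sample_random_effect_sd = sample_random_effect_sd,
              nb_dispersion = nb_dispersion,
              de_fraction = de_fraction, de_logfc = de_logfc,
              interaction_logfc = interaction_logfc,
              n_ctl_genes = n_ctl_genes, scenario = scenario,
              confound_strength = confound_strength, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_subjects", "n_samples_per_subject", "n_celltypes",
              "n_batches", "n_genes", "cells_per_sample_mean")
  for (f in counts)
    if (cfg[[f]] < 1) stopf("invalid config: %s must be >= 1", f)
  if (cfg$n_genes < 10) stopf("invalid config: n_genes must be >= 10")
  n_samples <- cfg$n_subjects * cfg$n_samples_per_subject
  if (n_samples < 2 * cfg$n_batches)
    stopf("invalid config: fewer than 2 samples per batch (%d samples, %d batches)",
          n_samples, cfg$n_batches)
  sds <- c("celltype_effect_sd", "batch_effect_sd", "batch_celltype_sd",
           "celltype_uv_factor_sd", "sample_random_effect_sd")
  for (f in sds)
    if (cfg[[f]] < 0) stopf("invalid config: %s must be >= 0", f)
  if (cfg$de_fraction < 0 || cfg$de_fraction >= 1)
    stopf("invalid config: de_fraction must be in [0, 1)")
  if (cfg$nb_dispersion <= 0) stopf("invalid config: nb_dispersion must be > 0")
  if (cfg$n_ctl_genes + round(cfg$de_fraction * cfg$n_genes) > cfg$n_genes)
    stopf("invalid config: control genes and DE genes exceed the gene count")
  invisible(cfg)
}

#' Assign mock treatments to samples
#'
#' Splits samples into mock treatments A and B under one of three scenarios:
#' \code{balanced} stratifies the two groups evenly within every batch;
#' \code{confounded} places a fraction \code{strength} of the treatment-A
#' samples into the first half of the batches (strength 1 with two batches
#' makes treatment identical to batch); \code{confounded_interaction} uses
#' the same confounded assignment -- the interaction with the second
#' biological covariate is introduced at spiking time, see
#' \code{\link{spike_de}}.
#'
#' @param sample_meta data.frame with columns \code{sample} and \code{batch},
#'   one row per single-cell sample.
#' @param scenario \code{"balanced"}, \code{"confounded"} or
#'   \code{"confounded_interaction"}.
#' @param strength confounding strength in \code{[0.5, 1]}.
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @return Named character vector (\code{"A"}/\code{"B"}) indexed by sample id.
#' @export
assign_mock_treatment <- function(sample_meta,
                                  scenario = c("balanced", "confounded",
                                               "confounded_interaction"),
                                  strength = 0.8, seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  batch <- factor(sample_meta$batch)
  if (nlevels(batch) < 2) stopf("need at least 2 batches")
  n <- nrow(sample_meta)
  trt <- character(n)
  if (scenario == "balanced") {
    for (b in levels(batch)) {
      idx <- which(batch == b)
      if (length(idx) < 2)
        stopf("batch '%s' has fewer than 2 samples; cannot stratify", b)
      lab <- rep(c("A", "B"), length.out = length(idx))
      trt[sample(idx)] <- lab
    }
  } else {
    half1 <- levels(batch)[seq_len(ceiling(nlevels(batch) / 2))]
    in1 <- which(batch %in% half1)
    in2 <- setdiff(seq_len(n), in1)
    n_a <- floor(n / 2)
    n_a1 <- min(round(strength * n_a), length(in1))
    n_a2 <- min(n_a - n_a1, length(in2))
    a_idx <- c(sample(in1, n_a1), if (n_a2 > 0) sample(in2, n_a2))
    trt[] <- "B"
    trt[a_idx] <- "A"
  }
  setNames(trt, as.character(sample_meta$sample))
}

#' Simulate a single-cell dataset with planted structure
#'
#' Generates negative-binomial cell-level counts with gene-specific cell-type
#' effects, gene-specific batch effects (the planted unwanted variation),
#' per-sample random effects (within-sample correlation), and, when
#' \code{de_fraction > 0}, differential expression spiked between two mock
#' treatment groups via \code{\link{spike_de}}. Ethnicity (two levels,
#' balanced over subjects) is carried as a second biological covariate.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{dataset} (a \code{\link{cell_dataset}}
#'   whose \code{cell_meta} has columns \code{sample}, \code{celltype},
#'   \code{subject}, \code{batch}, \code{ethnicity}, \code{treatment}) and
#'   \code{truth} (a \code{simulation_truth}: per-cell-type DE gene sets,
#'   treatment assignment, batch map, registered control genes, scenario).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$n_genes
  Tt <- config$n_celltypes
  L <- config$n_batches
  N <- config$n_subjects * config$n_samples_per_subject

  subjects <- sprintf("subj%02d", seq_len(config$n_subjects))
  samp <- data.frame(
    sample = sprintf("s%02d", seq_len(N)),
    subject = rep(subjects, each = config$n_samples_per_subject),
    stringsAsFactors = FALSE
  )
  # subjects round-robin over batches; technical replicates of one subject
  # cycle through further batches so replicate pairs straddle batches
  subj_batch <- (seq_len(config$n_subjects) - 1L) %% L
  rep_idx <- rep(seq_len(config$n_samples_per_subject) - 1L,
                 times = config$n_subjects)
  samp$batch <- sprintf("batch%d",
                        1L + (rep(subj_batch, each = config$n_samples_per_subject) +
                              rep_idx) %% L)
  # alternate ethnicity within each batch round, so ethnicity is balanced
  # across batches rather than collinear with them
  subj_eth <- c("eth1", "eth2")[1L + ((seq_len(config$n_subjects) - 1L) %/% L) %% 2L]
  samp$ethnicity <- subj_eth[rep(seq_len(config$n_subjects),
                                 each = config$n_samples_per_subject)]
  trt <- assign_mock_treatment(samp, config$scenario,
                               strength = config$confound_strength)
  samp$treatment <- unname(trt[samp$sample])

  genes <- sprintf("gene%04d", seq_len(G))
  base <- rnorm(G, config$baseline_logmean[[1]], config$baseline_logmean[[2]])
  ct_eff <- matrix(rnorm(Tt * G, 0, config$celltype_effect_sd), Tt, G)
  batch_eff <- matrix(rnorm(L * G, 0, config$batch_effect_sd), L, G)
  bc_eff <- if (config$batch_celltype_sd > 0)
    array(rnorm(L * Tt * G, 0, config$batch_celltype_sd), c(L, Tt, G))
  samp_eff <- matrix(rnorm(N * G, 0, config$sample_random_effect_sd), N, G)
  uvf_load <- if (config$celltype_uv_factor_sd > 0)
    rnorm(G, 0, config$celltype_uv_factor_sd)

  # log2 NB mean for each (sample, celltype) combination
  combo <- expand.grid(n = seq_len(N), t = seq_len(Tt))
  lmu <- matrix(rep(base, each = nrow(combo)), nrow(combo), G)
  bidx <- as.integer(sub("batch", "", samp$batch))
  uvf_scores <- if (!is.null(uvf_load))
    setNames(rnorm(nrow(combo)),
             sprintf("%s.ct%d", samp$sample[combo$n], combo$t))
  for (i in seq_len(nrow(combo))) {
    n <- combo$n[i]; t <- combo$t[i]; l <- bidx[n]
    lmu[i, ] <- lmu[i, ] + ct_eff[t, ] + batch_eff[l, ] + samp_eff[n, ]
    if (!is.null(bc_eff)) lmu[i, ] <- lmu[i, ] + bc_eff[l, t, ]
    if (!is.null(uvf_load)) lmu[i, ] <- lmu[i, ] + uvf_scores[i] * uvf_load
  }

  n_cells <- pmax(2L, rpois(N, config$cells_per_sample_mean))
  cell_sample <- rep(seq_len(N), n_cells)
  cell_type <- sample.int(Tt, length(cell_sample), replace = TRUE)
  cell_combo <- match(paste(cell_sample, cell_type),
                      paste(combo$n, combo$t))
  C <- length(cell_sample)
  mu <- 2^lmu[cell_combo, , drop = FALSE]
  counts <- matrix(rnbinom(C * G, size = 1 / config$nb_dispersion, mu = mu),
                   C, G)
  dimnames(counts) <- list(sprintf("cell%05d", seq_len(C)), genes)

  cell_meta <- data.frame(
    sample = samp$sample[cell_sample],
    celltype = sprintf("ct%d", cell_type),
    subject = samp$subject[cell_sample],
    batch = samp$batch[cell_sample],
    ethnicity = samp$ethnicity[cell_sample],
    treatment = samp$treatment[cell_sample],
    stringsAsFactors = FALSE
  )
  dataset <- cell_dataset(counts, cell_meta)

  ctl_genes <- if (config$n_ctl_genes > 0)
    sort(sample(genes, config$n_ctl_genes)) else character(0)
  truth <- structure(list(
    de_genes = setNames(rep(list(character(0)), Tt),
                        sprintf("ct%d", seq_len(Tt))),
    de_sign = NULL,
    assignment = trt,
    batch = setNames(samp$batch, samp$sample),
    ethnicity = setNames(samp$ethnicity, samp$sample),
    scenario = config$scenario,
    ctl_genes = ctl_genes,
    uv_factor_scores = uvf_scores
  ), class = "simulation_truth")

  if (config$de_fraction > 0) {
    sp <- spike_de(dataset, truth, config)
    dataset <- sp$dataset
    truth <- sp$truth
  }
  list(dataset = dataset, truth = truth)
}

#' Spike differential expression between mock treatments
#'
#' Multiplies the counts of the selected DE genes in treatment-B cells by
#' \code{2^(s_g * de_logfc)} with a per-gene sign \code{s_g} split 50/50, then
#' re-rounds to integers, so pseudobulk-level DE is induced coherently at the
#' cell level. Genes registered as negative controls are never spiked. Under
#' the \code{confounded_interaction} scenario, treatment-B cells of the
#' second ethnicity group receive an extra \code{2^(s_g * interaction_logfc)},
#' making a DEA model without the treatment-by-ethnicity interaction
#' misspecified.
#'
#' @param dataset a \code{\link{cell_dataset}} whose metadata has a
#'   \code{treatment} column.
#' @param truth a \code{simulation_truth} carrying the treatment assignment
#'   and registered control genes; spiked gene ids (and signs) are recorded in
#'   the returned copy.
#' @param config a \code{\link{sim_config}}.
#' @param genes optional explicit gene ids to spike; default draws
#'   \code{round(de_fraction * n_genes)} genes outside the control set using
#'   the current RNG stream.
#' @param seed optional seed; \code{NULL} continues the current RNG stream.
#' @return list with modified \code{dataset} and updated \code{truth}.
#' @export
spike_de <- function(dataset, truth, config, genes = NULL, seed = NULL) {
  stopifnot(inherits(dataset, "cell_dataset"))
  if (!is.null(seed)) set.seed(seed)
  all_genes <- colnames(dataset$counts)
  n_de <- round(config$de_fraction * length(all_genes))
  if (is.null(genes)) {
    if (n_de < 1) stopf("de_fraction * n_genes must be >= 1 to spike")
    genes <- sort(sample(setdiff(all_genes, truth$ctl_genes), n_de))
  }
  bad <- intersect(genes, truth$ctl_genes)
  if (length(bad) > 0)
    stopf("cannot spike registered negative-control genes: %s",
          paste(head(bad, 5), collapse = ", "))
  sgn <- sample(c(-1, 1), length(genes), replace = TRUE)
  names(sgn) <- genes

  meta <- dataset$cell_meta
  b_cells <- which(meta$treatment == "B")
  counts <- dataset$counts
  if (length(b_cells) > 0 && config$de_logfc != 0) {
    gi <- match(genes, all_genes)
    block <- as.matrix(counts[b_cells, gi, drop = FALSE])
    fc <- 2^(sgn * config$de_logfc)
    if (truth$scenario == "confounded_interaction" &&
        config$interaction_logfc != 0) {
      eth2 <- meta$ethnicity[b_cells] == "eth2"
      fc_mat <- matrix(fc, length(b_cells), length(genes), byrow = TRUE)
      fc_mat[eth2, ] <- fc_mat[eth2, ] *
        matrix(2^(sgn * config$interaction_logfc), sum(eth2), length(genes),
               byrow = TRUE)
      block <- round(block * fc_mat)
    } else {
      block <- round(sweep(block, 2, fc, `*`))
    }
    counts[b_cells, gi] <- block
    counts <- Matrix::drop0(counts)
  }
  dataset$counts <- counts
  truth$de_genes <- lapply(truth$de_genes, function(x) genes)
  truth$de_sign <- sgn
  list(dataset = dataset, truth = truth)
}

#' @exportS3Method base::print
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation_truth: scenario '%s', %d DE genes/cell type, %d controls\n",
              x$scenario, length(x$de_genes[[1]]), length(x$ctl_genes)))
  invisible(x)
}

#' Write simulation truth as JSON
#'
#' @param truth a \code{simulation_truth}.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
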