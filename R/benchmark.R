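# Simulation benchmark: generate datasets with spiked DE, apply a correction
# strategy, test per cell type, and score TPR/FDR against the planted truth
# at the nominal FDR levels.

#' Benchmark correction strategies on synthetic data
#'
#' For each replicate dataset and strategy, simulates a dataset from
#' \code{config}, estimates unwanted factors (where the strategy has any),
#' runs the per-cell-type DEA, calls genes at each nominal FDR level with
#' Benjamini-Hochberg, and scores TPR and empirical FDR against the spiked
#' truth.
#'
#' Strategies: \code{"UQ"} (no correction), \code{"UQ_batch"} (batch as a
#' fixed effect), \code{"RUV2_T1"}/\code{"RUV2_T2"}/\code{"RUV2_T3"} and the
#' \code{RUV4}/\code{RUVIII} analogues (RUV estimator x trail; RUVIII needs
#' technical replicates, i.e. \code{n_samples_per_subject > 1}), and
#' \code{"RUVIII_PBPS"} (per cell type, all genes as controls, PBPS
#' replicate structure). RUV2/RUV4/standard-RUVIII use the registered
#' negative-control genes when \code{config$n_ctl_genes > 0}, otherwise all
#' genes. Infeasible strategies are recorded as skipped, not errors.
#'
#' @param config a \code{\link{sim_config}} defining the study conditions
#'   (scenario, confounding strength, dimensions).
#' @param strategies character vector of strategy names (see Details).
#' @param n_datasets number of replicate datasets.
#' @param nominal nominal FDR levels for gene calling.
#' @param k_ruv factors for the RUV2/RUV4/RUVIII trails.
#' @param k_pbps factors for RUVIII-PBPS.
#' @param seed base seed; dataset d uses \code{seed + d - 1}.
#' @return data.frame with columns \code{seed}, \code{scenario},
#'   \code{strategy}, \code{celltype}, \code{nominal}, \code{tpr},
#'   \code{fdr}, \code{n_called}; skipped strategy/dataset combinations are
#'   in attribute \code{"skipped"}.
#' @export
run_benchmark <- function(config,
                          strategies = c("UQ", "UQ_batch", "RUV2_T2",
                                         "RUVIII_PBPS"),
                          n_datasets = 20,
                          nominal = c(0.01, 0.05, 0.10),
                          k_ruv = 5, k_pbps = 3, seed = 1) {
  rows <- list()
  skipped <- list()
  for (d in seq_len(n_datasets)) {
    cfg <- config
    cfg$seed <- seed + d - 1
    sim <- simulate_dataset(cfg)
    pb <- log2p1(uq_normalize(pseudobulk(sim$dataset, by = "sample_celltype")))
    for (strat in strategies) {
      sc <- tryCatch(
        score_strategy(strat, sim, pb, cfg, nominal, k_ruv, k_pbps),
        error = function(e) e)
      if (inherits(sc, "error")) {
        skipped[[length(skipped) + 1]] <- data.frame(
          seed = cfg$seed, strategy = strat,
          reason = conditionMessage(sc), stringsAsFactors = FALSE)
        next
      }
      sc$seed <- cfg$seed
      sc$scenario <- cfg$scenario
      rows[[length(rows) + 1]] <- sc
    }
  }
  if (length(rows) == 0) stopf("no strategy produced results")
  out <- do.call(rbind, rows)
  out <- out[, c("seed", "scenario", "strategy", "celltype", "nominal",
                 "tpr", "fdr", "n_called")]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
  out
}

# Runs one strategy on one simulated dataset; returns the score rows.
score_strategy <- function(strat, sim, pb, cfg, nominal, k_ruv, k_pbps) {
  meta <- pb$sample_meta
  truth <- sim$truth
  ctl <- if (length(truth$ctl_genes) > 0)
    colnames(pb$counts) %in% truth$ctl_genes
  else rep(TRUE, ncol(pb$counts))
  interact <- cfg$scenario == "confounded_interaction"

  W_list <- NULL
  batch_in_X <- FALSE
  if (strat == "UQ") {
    # no correction
  } else if (strat == "UQ_batch") {
    batch_in_X <- TRUE
  } else if (strat == "RUVIII_PBPS") {
    pcfg <- pbps_config(
      bio_covariates = c("treatment", "ethnicity", "celltype"),
      uv_covariates = "batch",
      n_pseudosamples = 10, seed = cfg$seed + 500000L)
    W_list <- suppressWarnings(
      ruviii_pbps(sim$dataset, pcfg, k = k_pbps))
  } else if (grepl("^(RUV2|RUV4|RUVIII)_T[123]$", strat)) {
    parts <- strsplit(strat, "_")[[1]]
    method <- parts[1]
    trail <- parts[2]
    rep_labels <- NULL
    if (method == "RUVIII") {
      if (cfg$n_samples_per_subject < 2)
        stopf("RUVIII without technical replicates is infeasible (use RUVIII_PBPS)")
      rep_labels <- setNames(as.character(sim$dataset$cell_meta$subject),
                             as.character(sim$dataset$cell_meta$sample))
      rep_labels <- rep_labels[!duplicated(names(rep_labels))]
    }
    spec <- trail_spec(trail = trail, method = method, k = k_ruv, ctl = ctl,
                       replicate_labels = rep_labels)
    W_list <- suppressWarnings(estimate_W(pb, spec, dataset = sim$dataset))
  } else {
    stopf("unknown strategy '%s'", strat)
  }

  celltypes <- sort(unique(as.character(meta$celltype)))
  out <- list()
  for (t in celltypes) {
    rows <- which(as.character(meta$celltype) == t)
    mt <- meta[rows, , drop = FALSE]
    fml <- if (interact) ~ treatment * ethnicity else ~ treatment + ethnicity
    if (batch_in_X)
      fml <- stats::update(fml, ~ . + batch)
    X <- model.matrix(fml, data = mt)
    W_t <- NULL
    if (!is.null(W_list)) {
      if (!t %in% names(W_list)) next  # skipped cell type
      W_t <- W_list[[t]][rownames(pb$logmat)[rows], , drop = FALSE]
    }
    fit <- fit_dea(pb$logmat[rows, , drop = FALSE], X, W = W_t,
                   contrast = "treatmentB")
    for (lv in nominal) {
      called <- call_deg(fit, lv)
      sc <- tpr_fdr(called, truth$de_genes[[t]])
      out[[length(out) + 1]] <- data.frame(
        strategy = strat, celltype = t, nominal = lv,
        tpr = sc[["tpr"]], fdr = sc[["fdr"]], n_called = length(called),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) stopf("no cell type could be scored")
  do.call(rbind, out)
}
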