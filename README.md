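# pbruv

Removing unwanted variation in pseudobulk differential expression analysis
of single-cell RNA-seq data.

## The problem

Pseudobulk analysis sums single-cell counts by sample and cell type and then
tests differential expression (DE) per cell type with bulk-style linear
models. Technical ("unwanted") variation — processing cohorts, reagent
batches, sequencing runs — contaminates those counts, and when it is
associated with the condition of interest (confounding), naive models
inflate the false discovery rate. RUV (remove unwanted variation) methods
estimate latent unwanted factors from the data and adjust the DE model with
them, based on the log-linear model

```
log2(Y) = W alpha + X beta + eps
```

where `Y` is the samples-by-genes pseudobulk matrix, `X` the design of
interest (Q columns), `W` the m-by-K matrix of unwanted factors and `alpha`
their gene loadings. The estimators differ in what anchors `W`:

* **RUV2** — factor analysis (truncated SVD) of negative-control genes,
  genes assumed unaffected by the condition;
* **RUV4** — loadings from the residuals of `log2(Y) = X beta + eps`,
  factors recovered from the control genes;
* **RUVIII** — loadings from differences between technical replicates
  (negative-control samples), factors recovered from control genes.

Because pseudobulk samples from one single-cell sample are correlated, there
are three ways ("trails") to run these estimators: **T1** on all pseudobulk
samples jointly, **T2** separately per cell type, **T3** once per
single-cell sample (cell types pooled, the factor row then broadcast to each
cell type). `pbruv` implements all nine combinations.

Most studies have neither technical replicates nor trustworthy
negative-control genes. **PBPS** (pseudobulk pseudosamples) fills that gap:
cells are stratified by biology `b` (condition x ethnicity x cell type) and
known technical level `l` (batch); within each stratum, `I` pseudosamples
are built by resampling `c_bar_b` cells with replacement and pseudobulking
them. Pseudosamples sharing `b` across batches act as surrogate technical
replicates, so RUVIII runs with *all genes* as controls
(`ruviii_pbps()`).

The package also ships the synthetic single-cell generator used to validate
all of this (multi-batch negative-binomial counts with within-sample
correlation and spiked DE between two mock treatments), per-cell-type DEA
with moderated t-statistics, and diagnostics (RLE, PCA silhouette widths,
TPR/FDR scoring, factor-batch association).

## Worked example

```r
library(pbruv)

# a confounded study: 16 samples, 4 batches, 2 cell types, 2000 genes,
# 10% of genes DE between two mock treatments, treatment-batch confounding
cfg <- sim_config(scenario = "confounded", n_ctl_genes = 200, seed = 3)
sim <- simulate_dataset(cfg)
pb  <- log2p1(uq_normalize(pseudobulk(sim$dataset)))

# is there batch structure? (average silhouette width of batches in PC space)
asw(pb$logmat, pb$sample_meta$batch, n_pcs = 10)$asw
#> [1] 0.3074376

# RUVIII-PBPS: pseudosamples as surrogate technical replicates
pcfg <- pbps_config(bio_covariates = c("treatment", "ethnicity", "celltype"),
                    uv_covariates = "batch", n_pseudosamples = 10, seed = 99)
W <- ruviii_pbps(sim$dataset, pcfg, k = 3)

# per-cell-type DEA with the estimated factors as covariates
rows <- which(pb$sample_meta$celltype == "ct1")
X <- model.matrix(~ treatment + ethnicity, pb$sample_meta[rows, ])
fit <- fit_dea(pb$logmat[rows, ], X,
               W = W[["ct1"]][rownames(pb$logmat)[rows], ],
               contrast = "treatmentB")
deg <- call_deg(fit, level = 0.10)
tpr_fdr(deg, sim$truth$de_genes$ct1)
#>       tpr       fdr
#> 0.9000000 0.1262136
```

90% of the spiked genes are recovered at a 10% nominal FDR with an
empirical FDR of 12.6%; the naive model without `W` on the same dataset
reaches only 78.5% power (and across replicate confounded datasets its mean
FDR inflates to roughly double the nominal level — see `run_benchmark()`
for the systematic comparison across strategies and scenarios).

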