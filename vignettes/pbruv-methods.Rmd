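---
title: "Models and methods behind pbruv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pbruv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pbruv)
```

This vignette documents the statistical model the package implements, the
assumptions behind each component, the defaults and why they were chosen,
and what the synthetic-data validation does and does not establish about
real data.

## The model

All estimators work on the log-linear model for a samples-by-genes
pseudobulk expression matrix,

$$\log_2(Y) = W\alpha + X\beta + \varepsilon,$$

with $X$ ($m \times Q$) the design of interest, $W$ ($m \times K$) latent
unwanted factors, $\alpha$ ($K \times G$) their gene loadings. "Factor
analysis" is implemented as truncated SVD throughout — no rotation, no
maximum-likelihood factor model — matching the classical RUV estimators.
Pseudobulk counts are upper-quartile normalized and transformed as
$\log_2(\cdot + 1)$ before estimation; the pseudo-count avoids logarithms
of zero and the transform order (normalize, then log) follows standard
practice.

Differential expression is **not** run on the factor-removed matrix
$Y^* = Y - W\alpha$ (that risks removing biology); $Y^*$ is for diagnostics
only. Instead `fit_dea()` fits, per gene, OLS of $\log_2(Y_t)$ on
$[X \,|\, W_t]$ and tests the contrast of interest with a moderated
t-statistic.

## Estimators

* `ruv2(Y, ctl, k)`: SVD of the column-centered control-gene submatrix;
  $W$ = first $k$ left singular vectors scaled by singular values, loadings
  by OLS of the full matrix on $W$. Controls are centered with an intercept
  only; they are assumed unaffected by the design (a `design` argument
  exposes conditional estimation for users who doubt that assumption, off
  by default).
* `ruv4(Y, X, ctl, k)`: loadings from the SVD of the design residuals
  $(I - P_X)Y$; factors recovered from the column-centered control genes,
  $W = Y^{c}_{ctl}\,\alpha_{ctl}' (\alpha_{ctl}\alpha_{ctl}')^{-1}$.
  Centering here plays the role of the intercept-removal preprocessing of
  the classical four-step procedure; without it, gene means leak a
  constant component into $W$ (harmless in a DEA with an intercept, but it
  breaks the identity with `ruv2` on degenerate designs and makes the
  factors harder to interpret).
* `ruviii(Y, M, ctl, k)`: loadings from the SVD of the replicate residuals
  $(I - P_M)Y$, where $M$ maps samples to technical-replicate groups;
  factor recovery as in RUV4 but from the uncentered controls, and the
  normalized matrix $Y^* = Y - W\alpha$ is returned (it reproduces the
  closed-form property that replicates differing only by a gene-wise shift
  become identical).

Numerical choices: SVD signs are fixed (the largest-absolute loading of
each factor is made positive) so results are reproducible across BLAS
implementations; near-singular $\alpha_{ctl}\alpha_{ctl}'$ is solved by a
pseudo-inverse with relative tolerance $10^{-10}$ plus a warning, so tiny
control sets degrade gracefully instead of crashing; degenerate inputs
(rank below $k$) are errors, not silent truncations.

## Trails

`estimate_W()` applies an estimator under three strategies. T1 treats all
pseudobulk samples as independent (they are not: rows from one single-cell
sample are correlated) and partitions $W$ by cell type afterwards; its
design is the cell-means coding of cell type crossed with the factor of
interest. T2 fits each cell type separately — all rows independent, at the
cost of ignoring shared information. T3 pools cell types per single-cell
sample, estimates one $W_N$, and broadcasts rows; it assumes technical
noise does not interact with cell type. For RUVIII the replicate grouping
is subject-by-cell-type under T1, subject within cell type under T2, and
subject under T3 — replicates must share biology, and the per-trail
grouping follows from that requirement.

A consequence worth stating: when an unwanted factor is *categorical and
shared* (the same batch label for every cell type of a sample), T2 and T3
span the same sample-space correction, because the per-gene DEA re-fits
loadings freely. T3 genuinely loses power only when factor *scores* differ
between cell types of one sample (e.g. cell-quality effects hitting one
cell type harder). The generator exposes exactly that structure
(`celltype_uv_factor_sd`) for validation.

## PBPS

`generate_pbps()` implements the pseudosample algorithm: stratify cells by
biology $b$ and known technical level $l$; compute $\bar c_b$, the average
number of cells contributed per single-cell sample within $b$; draw $I$
multisets of $\bar c_b$ cells with replacement from each non-empty stratum
and pseudobulk them. Assumptions: (1) at least one technical covariate is
known; (2) cells with the same biology and technical exposure are
exchangeable; (3) differences between same-biology pseudosamples across
technical levels are mainly unwanted variation. Under (3),
`pbps_replicate_structure()` places all pseudosamples of one biological
subgroup in one replicate group (across $l$ and draws) and leaves original
samples as singletons (real technical-replicate labels, when supplied, are
honored). `ruviii_pbps()` then runs RUVIII per cell type (the
best-performing trail) on the augmented matrix with **all genes as
controls**, and discards pseudosample rows afterwards.

Open choices resolved here, configurable where reasonable: the fractional
$\bar c_b$ is rounded to the nearest integer (minimum 1; floor/ceiling
available); pseudosamples participate in the upper-quartile normalization
of the augmented per-cell-type matrix, since they must share the originals'
scale for the replicate residuals to be meaningful; $I = 10$ by default
(the choice is known to be somewhat arbitrary and is exposed).

## DEA

Gene-wise OLS with closed-form matrix algebra; residual degrees of freedom
$S_t - Q - K$; empirical-Bayes variance moderation via
`limma::squeezeVar()` (default on; the moderated statistics match
`limma::lmFit`/`eBayes` exactly, which the test suite verifies), BH
adjustment within cell type. The engine is log-linear rather than a
negative-binomial GLM for internal consistency with the factor model above;
NB-based RUV variants are deliberately out of scope. For the misspecified
scenario the model formula accepts a treatment-by-ethnicity interaction.
Numerically perfect fits (residual variance at rounding-noise level) are
reported as $p = 1$ when the effect is also zero and $p = 0$ otherwise,
rather than leaving 0/0 artifacts.

## The synthetic generator

`simulate_dataset()` draws negative-binomial cell counts with a log2-linear
mean: per-gene baselines $\sim N(-1, 2)$ (log2 counts per cell), gene-wise
cell-type effects (sd 0.5), gene-wise batch effects (sd 0.5), a per-sample
per-gene random effect (sd 0.15) inducing within-sample correlation, and NB
dispersion 0.3. Defaults: 16 subjects, one sample each, 2 cell types, 4
batches, 2000 genes, ~100 cells per sample. DE is spiked in 10% of genes by
scaling treatment-B cells by $2^{\pm 1}$ (sign split 50/50) before
pseudobulking, so pseudobulk DE is induced coherently at the cell level;
registered negative-control genes are never spiked. Three assignment
scenarios: balanced (treatments stratified within batch), confounded (80%
of treatment-A samples in one half of the batches by default), and
confounded-with-interaction (the spiked effect additionally differs by
ethnicity, so a DEA without the interaction term is misspecified).

Why these values: the batch-effect spread was chosen so the batch
structure of the simulated pseudobulk (average silhouette width ~0.53 on 2
PCs, ~0.36 on 10 PCs for one cell type) is comparable to what strong
processing-cohort effects look like in real PBMC pseudobulk data; 4
batches and ~10% DE mirror a typical multi-cohort design; 16 samples keeps
a full benchmark run (20 replicate datasets times several strategies)
around a minute on one CPU, and the problem sizes quoted in the tests are
the package's own validation scale. The generator does **not** attempt to
match any real dataset's empirical distributions: no doublets, no ambient
RNA, no cell-type misclassification, no library-size outliers, and batch
effects are Gaussian in log space. Passing tests therefore establish the
estimators' algebra, calibration under the stated model, and the relative
ordering of strategies — not performance guarantees on any particular real
dataset.

## What the validation shows

With the defaults above, across 20 replicate confounded datasets: the
uncorrected model's empirical FDR at the 10% nominal level roughly doubles
the nominal value; RUV2 per cell type (trail T2, $K=5$, held-out control
genes) controls it; RUVIII-PBPS ($K=3$, $I=10$, all genes as controls)
restores most of the control while clearly beating the uncorrected model at
every nominal level and keeping the highest power. A residual excess of
roughly 2 percentage points above the nominal 10% remains for RUVIII-PBPS
at this sample size (16 samples): the estimated factors absorb a small
amount of sample-specific noise, which deflates residual standard errors
(null-t standard deviation ~1.14 where ~1.05 is expected), and loadings
estimated from resampled pseudosamples leave a small fraction of the batch
subspace uncaptured. This is a property of data-driven factor covariates at
modest sample sizes, not of the implementation — supplying the true batch
labels as fixed effects in the same pipeline yields 9.9%. The effect
shrinks with more samples and with stronger batch signal.

## Known limitations

* No automatic selection of $K$; no NB-GLM estimation; no mixed-model
  treatment of within-individual correlation beyond the trail mechanics.
* PBPS requires the biological and technical covariates to be known and
  categorical; misspecified biology in $b$ converts biological signal into
  "unwanted" variation.
* The UQ normalization uses nonzero-count quartiles rescaled to geometric
  mean 1; other conventions differ by per-sample constants.
* The number of pseudosamples $I$ is not optimized; variance-based
  selection is future work.
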