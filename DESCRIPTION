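Package: pbruv
Title: Removing Unwanted Variation in Pseudobulk Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and removing unwanted (technical) variation in
    pseudobulk differential expression analyses of single-cell RNA-seq data.
    Implements pseudobulk aggregation with upper-quartile normalization, the
    RUV2, RUV4 and RUVIII factor estimators under three application strategies
    ("trails": all samples jointly, per cell type, or per single-cell sample),
    and pseudobulk pseudosamples (PBPS): artificial technical replicates built
    by resampling cells within biology-by-batch strata, which let RUVIII run
    with all genes as negative controls when real technical replicates or
    trustworthy negative-control genes are unavailable. Includes per-cell-type
    differential expression with estimated factors as covariates, a synthetic
    multi-batch single-cell data generator with spiked differential expression,
    and benchmarking diagnostics (RLE, PCA silhouette widths, TPR/FDR against
    simulation truth).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
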