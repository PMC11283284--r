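# scevlink

Does chromatin accessibility explain why some genes are noisy? Within a
homogeneous cell population, genes differ widely in their cell-to-cell
expression variability (scEV, "expression noise"), and the regulatory origin
of that variability is an open question. With paired single-cell multiome
data — scATAC-seq and scRNA-seq measured in the *same* cells — one can ask
the question directly: if a gene's expression fluctuations track its
chromatin state, then that gene's expression should be *predictable* from
its accessibility peaks, and highly variable genes (HVGs) should be better
predicted than stably expressed ones.

`scevlink` implements that testing pipeline for R users working with
single-cell multiome data, plus a synthetic multiome generator with known
ground truth so the whole chain is testable without any real dataset.

## The method

Let `X ∈ R^{N×p}` be the cell-by-peak accessibility matrix (TF-IDF
transformed) and `Y ∈ R^{N×q}` the cell-by-gene expression matrix
(library-size normalized, log1p). For each gene *j* the pipeline fits
predictive models of `y_j` from `X` over repeated 70/30 train/test splits
and scores each model by the average test-set Pearson correlation *r*:

* **Global models** (all peaks): k-nearest neighbours on the Jaccard
  similarity of peak supports (`a1/(a1+a2+a3)`, k = 10); lasso
  `min_{α,β} ||y_j − α − Xβ||² + λ||β||₁` with λ chosen by BIC subject to
  ≥ 5 selected peaks; lasso on 100-kb fused peak bins; gradient-boosted
  trees (10 trees); and a `p–128–64–1` feed-forward network with ReLU,
  dropout 0.2 and Adam on fused, [0, 1]-scaled inputs.
* **Local models** (peaks within 1.2 Mbp of the gene start): the
  unsupervised gene activity score
  `GS_cj = Σ_peaks (e^{−|d|/5000} + e^{−1}) · g_j · x_cp`, where *d* is the
  start-to-start distance and `g_j` is the inverse gene size rescaled to
  [1, 5]; and a lasso restricted to the local window (LocReg).

scEV is scored by two detectors on the raw counts of the selected
homogeneous cells: **vst** (variance of standardized counts after a loess
fit of log variance on log mean) and **splinefit** (signed distance to a 3-D
spline through dropout rate, log mean and log CV). The top-K genes per
detector are the HVGs.

Three one-sided tests link prediction to variability: a Wilcoxon rank-sum
test of *r* for HVGs vs non-HVGs, the Spearman correlation between *r* and
the scEV score across genes, and a Fisher (hypergeometric) test of the
overlap between the top-K1 well-predicted genes and the top-K2 HVGs — plus a
matched-mean control pairing each HVG with the non-HVG of closest mean
expression.

## Worked example

Simulate a paired multiome in which 20% of genes have their expression
variability driven by five accessibility peaks (three local, two distal),
then run the full pipeline:

```r
library(scevlink)

params <- sim_params(n_cells = 300, n_peaks = 1000, n_genes = 150,
                     n_chromosomes = 2, chrom_length = 1e7,
                     fraction_coupled = 0.2, coupling_strength = 1.5, seed = 7)
sim <- simulate_multiome(params)

cfg <- scev_config(min_peaks_per_cell = 20, min_genes_per_cell = 20,
                   min_cells_per_gene = 75, n_homogeneous_cells = 250,
                   K = 30, K1 = 30, K2 = c(30, 75), seed = 7)
res <- scev_pipeline(sim$multiome, cfg, models = c("knn", "lasso", "gs", "locreg"))
summary(res)
```

```
Accessibility vs expression variability: test summary
  knn        x vst       Wilcoxon p = 1.95e-06 (median r 0.083 vs 0.004), Spearman rho = 0.217 (p = 0.0042)
  knn        x splinefit Wilcoxon p = 2.82e-06 (median r 0.083 vs 0.004), Spearman rho = 0.264 (p = 0.000627)
  lasso      x vst       Wilcoxon p = 6.4e-13 (median r 0.356 vs -0.024), Spearman rho = 0.464 (p = 1.62e-09)
  lasso      x splinefit Wilcoxon p = 6.61e-14 (median r 0.356 vs -0.028), Spearman rho = 0.510 (p = 2.11e-11)
  gs         x vst       Wilcoxon p = 0.000152 (median r 0.068 vs 0.009), Spearman rho = 0.240 (p = 0.00173)
  gs         x splinefit Wilcoxon p = 8.15e-05 (median r 0.070 vs 0.009), Spearman rho = 0.220 (p = 0.00373)
  locreg     x vst       Wilcoxon p = 3.29e-13 (median r 0.338 vs -0.020), Spearman rho = 0.394 (p = 3.84e-07)
  locreg     x splinefit Wilcoxon p = 3.31e-14 (median r 0.338 vs -0.021), Spearman rho = 0.441 (p = 1.16e-08)
```

Every model predicts the accessibility-coupled HVGs far better than the
rest (for the lasso, median test *r* of 0.356 for HVGs against ≈ 0 for
non-HVGs), and the Spearman correlation between predictability and scEV is
strongly positive — the signature of epigenetically controlled expression
noise. The planted signal is recovered: 25 of the top 30 well-predicted
genes under the lasso are truly coupled genes,

```r
top <- rank_well_predicted(res$performance, "lasso", 30)
sum(top %in% sim$truth$coupled_gene_ids)
#> 25
```

and the top-30 well-predicted set overlaps the top-30 HVGs in 25/30 genes
(Fisher p = 1.5e-18; `res$report$overlaps`). Set `coupling_strength = 0`
and every one of these signals disappears — the pipeline's tests stay
calibrated under the null.

Individual stages are exported for standalone use: `qc_filter()`,
`tfidf_transform()`, `normalize_rna()`, `select_homogeneous_cells()`,
`knn_predict()`, `fit_lasso_bic()`, `peak_fusion()`, `fit_gbt()`,
`fit_mnn()`, `gene_score()`, `fit_locreg()`, `vst_scev()`,
`splinefit_scev()`, `wilcoxon_hvg_test()`, `overlap_fisher()`,
`matched_mean_sensitivity()` and friends. On-disk interchange uses
MatrixMarket triplets plus id files (`read_count_matrix()`), TSV/BED
interval tables and YAML configuration (`load_config()`).

## Limitations

The simulator emulates the statistical character of droplet multiome data
(extreme ATAC sparsity, overdispersed RNA counts, dropout, library-size
variation), not its biology: no TAD structure, promoter/enhancer annotation
or sequence content. Results on synthetic data demonstrate that the
pipeline recovers a planted accessibility→expression coupling and stays
calibrated without one; they do not by themselves certify biological
conclusions on real data. See the methods vignette
(`vignettes/accessibility-expression-variability.Rmd`) for the full model
description, parameter choices and numerical conventions.
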