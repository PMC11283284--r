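---
title: "Testing epigenetic control of single-cell expression variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing epigenetic control of single-cell expression variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the testing strategy

Within one homogeneous cell population, genes differ in how much their
expression fluctuates from cell to cell (single-cell expression
variability, scEV). If those fluctuations are driven by cell-to-cell
differences in chromatin state, then a gene's expression should be
*predictable* from the same cell's accessibility peaks, and highly variable
genes (HVGs) should be more predictable than stably expressed genes.
`scevlink` operationalizes this as a statistical pipeline on paired
scATAC-seq/scRNA-seq data:

1. **Preprocess**: quality-control filtering, TF-IDF transform of the peak
   counts, library-size/log normalization of the expression counts, and
   restriction to a homogeneous cell subpopulation.
2. **Predict**: for each gene, fit a panel of supervised and unsupervised
   models of expression from accessibility over repeated 70/30
   train/test splits; score each (gene, model) by the average test-set
   Pearson correlation.
3. **Score variability**: rank genes by two scEV detectors on the raw
   counts; flag the top K as HVGs.
4. **Compare**: one-sided Wilcoxon (HVG vs non-HVG performance), Spearman
   (performance vs scEV level), Fisher (overlap of well-predicted genes
   with HVGs), and a matched-mean paired control.

The package's central assumption is the same as the field's: prediction
performance of accessibility on expression is a meaningful proxy for the
strength of epigenetic control of that gene. The pipeline never claims a
causal direction; it quantifies association under a fixed, seeded,
reproducible protocol.

# Preprocessing conventions

Filters run in a pinned order, because order changes boundary cases:
features on excluded chromosomes (default `chrX`, `chrY`, `chrM`) or
overlapping a blacklist interval by at least 1 bp are removed first; then
cells with too few nonzero peaks; then cells with too few expressed genes
(a cell removed by either modality leaves both); finally genes expressed in
too few retained cells or with mean raw count below the threshold. The
mean-expression filter is evaluated on **raw counts** with a keep condition
of `mean >= 0.5`, since filtering precedes normalization in the protocol.

The TF-IDF variant is fixed to `log(1 + 10^4 · TF · IDF)` with
`TF = x / rowSum` and `IDF = N / n_cells_with_peak`. This is the dominant
dialect in single-cell ATAC practice; it preserves zeros and is monotone in
each entry given the rest of the cell's row. The scaling constant (10^4)
and the option to drop the first component of the linear reduction (the
LSI depth-component convention) are exposed in the configuration; defaults
keep the constant at 10^4 and retain component 1, since the reduction is
specified as a plain truncated PCA.

Homogeneous-cell selection reduces the TF-IDF matrix to 50 dimensions
(truncated PCA), embeds those in 2-D with UMAP under a fixed seed, and
takes the `n` cells nearest to a *core cell*. Manual core picking is not
reproducible, so the default core is the cell nearest the coordinate-wise
median of the embedding (a medoid-style rule); an explicit
`core_cell = <id>` reproduces a manual choice. Ties in the distance
ordering break by cell id.

# The predictor panel

* **KNN** (global): cell-cell similarity is the Jaccard index of the
  *nonzero supports*, `a1/(a1+a2+a3)`; predictions average the expression
  of the k = 10 most similar training cells, ties broken by training-cell
  order. Two all-zero cells have similarity 0 by convention.
* **Lasso** (global): a 50-value log-spaced penalty path from
  `lambda_max` (all coefficients zero) down to `10^-3 · lambda_max`,
  predictors standardized internally, constant columns dropped. The
  penalty is chosen by Gaussian BIC, `n log(RSS/n) + df log n` with
  `df = |nonzero coefficients|`, restricted to path models with at least
  5 selected peaks ("no trivial models"). **Numerical guard**: with
  p ≫ n the small-penalty end of the path approaches interpolation,
  RSS → 0, and the Gaussian BIC diverges to −∞, which would always select
  a near-saturated model; the BIC argmin is therefore restricted to models
  with `df ≤ n/2`, the regime where the criterion is meaningful. If no
  path model reaches the minimum support, the smallest-penalty model is
  returned with a warning.
* **PeakFusion** (global): peaks are summed into fixed 100-kb bins keyed by
  `(chrom, floor(start / window))` — half-open, so a peak starting exactly
  at 100 000 opens a new bin — and the lasso runs on the fused matrix.
  Per-cell total signal is conserved by construction.
* **GBT** (global): gradient-boosted regression trees, 10 rounds,
  squared-error loss, library defaults otherwise, single-threaded and
  seeded for determinism.
* **MNN** (global): a `p–128–64–1` fully connected network on fused,
  min-max [0, 1]-scaled inputs (training ranges; test values clipped),
  ReLU activations, inverted dropout 0.2 after each hidden layer, MSE
  loss, Adam on shuffled mini-batches (30 epochs, batch 64, lr 10^-3).
  The optimizer settings are not prescribed anywhere authoritative, so
  they are fixed defaults, all overridable and all seeded. The output
  layer starts at the bias-only solution (zero weights, bias = mean of
  the training response): with a short, fixed training budget a generic
  initialization cannot even represent a constant target cleanly, and
  the bias-only start is exact there while leaving the rest of the fit
  unchanged.
* **GS** (local, unsupervised): for peaks whose start lies within 1.2 Mbp
  of the gene start on the same chromosome,
  `weight = exp(−|d|/5000) + exp(−1)` (start-to-start distance `d`, strand
  ignored), multiplied by the gene's inverse-size factor rescaled linearly
  across genes to [1, 5] (smallest gene → 5). The per-cell score is the
  weighted sum of transformed peak values. It is evaluated directly on
  test cells; there is nothing to train. A gene with no peak in its
  window scores 0 in every cell and is flagged, so its correlation
  degenerates to 0 rather than NaN. When all genes share one size the
  rescale collapses and the factor is 3 (midpoint) for everyone.
* **LocReg** (local): the lasso restricted to the 1.2-Mbp window, with the
  minimum-support constraint relaxed to `min(5, #window peaks)`.

Distances are measured start-to-start exactly as the GS formula prints
them, ignoring strand; a strand-aware TSS variant would change distances
for minus-strand genes and is deliberately not the default, to keep the
published formula literal.

## Evaluation harness

One split plan — `n_splits = 5` random 70/30 partitions with distinct
derived seeds — is built per run and reused for **every gene and every
model**, so model and gene comparisons are paired. Supervised fits see
training cells only; standardization, min-max ranges and penalty paths are
computed on the training fold. Pearson correlations on a fold where either
the truth or the prediction is constant are **defined as 0** and flagged:
dropping such folds would bias the per-gene averages, and near-zero median
performance across genes is an expected feature of this data type, not an
error state. Well-predicted genes are the top K1 by average correlation,
ties broken by gene id.

# scEV detectors

**vst**: per gene, a loess curve (span 0.3, degree 2 — the convention of
the standardized-variance method in mainstream single-cell toolkits) of
log10 variance on log10 mean of raw counts; counts standardized by the
observed mean and the curve-implied standard deviation; standardized values
clipped at `sqrt(N)`; the score is the variance of the clipped values.
Genes with zero variance score 0 and are excluded from the fit. The
implementation agrees with the Seurat reference implementation to within
10^-10 on simulated counts (cross-checked in the test suite).

**splinefit**: genes are placed in 3-D — dropout rate, log mean, log CV —
each coordinate z-scored across genes; a cubic smoothing spline of each
coordinate is fitted against the normalized log-mean rank (stiffness by
GCV, with a fixed-df fallback for strict determinism needs); the score is
the Euclidean distance to the fitted curve point, **signed** by the gene's
position above or below the curve in the variability coordinate. The sign
is a deliberate choice: an unsigned "distance from the curve" would rank
unusually *stable* genes as HVGs too, contradicting the detector's
purpose. The third coordinate is log CV by default (that is what the
method's reference figure plots) with log variance available as an option,
since written descriptions of the method disagree with its figures.

HVG selection is exact-K: descending score, ties by gene id.

# The comparison layer

All tests are one-sided in the direction under investigation (HVGs better
predicted; overlap enriched), since the pipeline exists to test a
directional hypothesis. Wilcoxon uses exact enumeration for tie-free groups
of ≤ 20 and the tie-corrected normal approximation otherwise; a fully tied
comparison returns p = 1 rather than NaN. The Fisher test is the one-sided
hypergeometric tail; the implementation is checked against exhaustive
enumeration for universes up to 50 genes. Spearman uses average ranks and
the one-sided t approximation. The matched-mean control pairs each HVG
(descending scEV order) with the unused non-HVG of closest mean expression
— **without replacement**, to avoid pseudo-replication in the paired
signed-rank test — with ties broken by gene id. No multiple-testing
correction is applied to the headline values (the report carries a
Bonferroni column for transparency), matching how such pipelines are
conventionally reported.

# The synthetic multiome generator

`simulate_multiome()` provides ground truth the real data cannot: a known
set of *coupled* genes whose expression variability is driven by
accessibility, with known driver peaks.

**What it emulates.** Peak widths uniform on 200–1000 bp and genomic
placement on model chromosomes; extreme ATAC sparsity (target zero
fraction 0.92, calibrated numerically by solving for the global rate, so
the realized value lands within a point or two of the target); log-normal
ATAC cell depths and RNA library sizes (sdlog 0.3); log-normal gene base
means (meanlog log 2, sdlog 0.8); negative-binomial RNA counts (size 8)
with independent 5% dropout.

**The coupling mechanism.** Each coupled gene has 5 driver peaks — 3
within the 1.2-Mbp local window of the gene start, 2 anywhere — and a
per-cell latent activity factor. Driver peaks share that factor
(`driver_cor = 0.6` of their latent variance), are drawn from the
more-accessible half of peaks, and are disjoint across genes. The gene's
per-cell log mean is shifted by `coupling_strength ×` the standardized sum
of its drivers' latent log-accessibility, centred by `−k²/2` so the
*mean* expression is unchanged — only the variance grows. Three of these
choices deserve their rationale spelled out: a shared factor is what makes
individual noisy peak counts informative about the gene (fully independent
driver latents dilute each peak's signal below the noise floor of
thousands of candidate peaks, and co-regulated enhancers do covary in real
data); accessible drivers matter because a peak observed as zero in 97% of
cells carries almost no information regardless of its latent state; and
mean-centring is what makes the matched-mean control a genuine control —
coupled genes differ from the rest in variance, not in mean. Crucially,
the *latent* accessibility drives expression, and the observed counts are
noisy readouts on both sides, so prediction performance is bounded well
away from 1 even for coupled genes — the realistic regime.

At `coupling_strength = 0` the coupled labels are exchangeable with the
rest by construction; this is the null model used to verify calibration.

**What it does not emulate.** Genome annotation structure (TADs,
promoters/enhancers), sequence content, doublets, batch effects,
gene-length-biased dropout, or correlated ATAC/RNA depth per cell. Passing
tests on this generator therefore demonstrate that the pipeline recovers a
planted accessibility→expression coupling and stays calibrated in its
absence — not that any particular biological claim holds on real data.

# Problem sizes and configuration scaling

The package's reference simulation is 600 cells × 3000 peaks × 400 genes
with 10% coupled genes, chosen so a complete pipeline run (four predictors,
five splits) takes on the order of a minute or two on one CPU while leaving
every statistical signal comfortably detectable. The paper-scale
configuration defaults (≥ 1000 peaks per cell, genes expressed in ≥ 200
cells, K = 200 HVGs) are sized for real experiments with hundreds of
thousands of peaks; at simulation scale they would be absurd (K = 200 of
400 genes is half the transcriptome). `scev_config_sim()` therefore scales
them: ≥ 50 peaks and ≥ 50 genes per cell, genes in ≥ 100 cells, 500
homogeneous cells, and K = K1 = K2 = 40 — 10% of genes, matching the
simulated coupled fraction, and proportionally close to the 2% that
K = 200 represents on a ~10 000-gene experiment.

# Known limitations

* The local window and GS distances are start-to-start and
  strand-agnostic; genes on the minus strand have their "promoter end" at
  `end`, which the default convention ignores.
* The BIC support-size guard (`df ≤ n/2`) is a pragmatic fix for the
  p ≫ n interpolation regime; information criteria on lasso paths remain
  heuristic there.
* The MNN predictor is sized for CPU training on fused bins; it is not a
  tuned deep model, and its fixed 30-epoch budget underfits strong
  nonlinearities by design.
* `splinefit` stiffness under GCV can shift slightly between BLAS builds;
  use the `df` argument where byte-level reproducibility across machines
  matters (within one machine all outputs are deterministic by seed).
* The two detectors share inputs, so their agreement (reported as a
  Spearman correlation and an HVG-overlap fraction) is a consistency
  check, not independent evidence.
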