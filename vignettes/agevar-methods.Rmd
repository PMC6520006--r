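---
title: "Age-related differential variability of gene expression: methods"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-related differential variability of gene expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agevar)
```

# Scope

`agevar` analyzes how the *inter-individual variability* of gene
expression — not just its mean level — changes with adult age. Given a
gene-by-sample expression matrix (log2 scale, e.g. microarray or
log-transformed RNA-seq) and sample metadata with ages and technical
covariates, the package provides:

1. a differential expression (DE) model with a transformed age predictor,
2. two differential variability (DV) statistics — a continuous
   residual-based one and a grouped IQR-based one with a subsampling null,
3. preranked gene-set enrichment and pathway score-distribution summaries,
4. association checks between mean and variability changes, between gene
   lists, and against external per-gene scores,
5. a synthetic-data generator that plants known mean and variance trends,
   used throughout the test suite and the acceptance script.

# Differential expression model

For gene $i$ with expression $Y_{ij}$ in sample $j$ of age $a_j$:

$$Y_{ij} = \beta_{i0} + \beta_{i1}\, a_j^{1/4} + \mathbf{x}_j^\top
\boldsymbol\gamma_i + \varepsilon_{ij}$$

The fourth-root transform linearizes expression-age trajectories that
change quickly in early adulthood and flatten later, a shape typical of
brain expression data; the exponent is a parameter (`age_exponent`) and
`fit_gene_model` can refit with exponent 1 to check that gene ranking by
slope is robust to the transform. Covariates $\mathbf{x}_j$ (sex, batch,
post-mortem interval, RIN, pH, ...) are dummy-coded with sorted factor
levels; the design is shared by all genes, so the whole matrix is fit with
one `lm.fit` call. The age slope's $t$-statistic uses the usual OLS
standard error; genes are classified up/down/null from the sign of
$\beta_{i1}$ at a Benjamini–Hochberg threshold of $q \le 0.05$
(inclusive).

Exact fits are handled explicitly: when the residual variance is at
floating-point noise level, a nonzero slope gets $p = 0$ and a zero slope
is reported as degenerate ($p = 1$) rather than letting noise ranks
produce an arbitrary answer.

# Differential variability

## Continuous statistic: $\Delta var(\rho)$

The DE model's absolute residuals $|\hat\varepsilon_{ij}|$ measure each
sample's deviation from the gene's age trend. The continuous DV statistic
is the Spearman correlation between $|\hat\varepsilon_{ij}|$ and age;
positive values mean the spread around the trend grows with age. The
$p$-value uses the $t$ approximation to the rank correlation (the same
approximation for every $n$, so results are continuous in the sample
size), followed by BH adjustment. Genes whose residual scale is
negligible relative to their expression scale are flagged degenerate and
reported with $\rho = 0$, $p = 1$: ranking numerical noise would
otherwise manufacture spurious correlations.

## Grouped statistic: $\Delta var(IQR)$ with a subsampling null

Samples are split into a young group ($n_y$ samples, ages 20–40 by
default) and an old group ($k$ samples, ages 60–80); middle-aged samples
are deliberately excluded, which the test suite verifies by perturbing
them. Because the IQR is biased by sample size, the young group is not
summarized by a single IQR: instead `dvar_grouped` draws $B$
without-replacement subsamples of size $k$ from the young group and
records each subsample's IQR (type-7 quantiles throughout). The statistic
is the fractional change

$$\Delta var(IQR) = \frac{IQR_{old} - \overline{IQR}_{young}}
{\overline{IQR}_{young}},$$

with the bar denoting the mean over subsamples, and the empirical
$p$-value doubles the smaller tail fraction of the null at $IQR_{old}$
(add-one corrected in sampled mode; exact fractions when
$\binom{n_y}{k}$ is small enough that all subsets are enumerated —
controlled by `exhaustive_limit`).

**Implementation.** One set of subsample index vectors is shared by all
genes in a run: each resample then reduces to a single C-level row-sort of
the young submatrix followed by a vectorized row-IQR, which makes 2,000
genes × 1,000 resamples run in about a second. Sharing indices across
genes leaves each gene's null a valid subsampling distribution and makes
the run deterministic given `seed`.

**Known limitation: the subsampling null is anti-conservative.** The null
distribution conditions on the observed young sample, so it captures only
the variation of a size-$k$ subsample *within* that fixed sample. It
omits (i) the old group's independent sampling variation and (ii) the
variation of the young sample itself around the population. For a
mean-like statistic the null SD scales as $\sigma\sqrt{1/k - 1/n_y}$
while the true spread of the observed statistic scales as
$\sigma\sqrt{1/k + 1/n_y}$; at $n_y = 53$, $k = 22$ that is a ratio of
about 1.56, and Monte-Carlo simulation of the exact procedure on null
genes shows a type-I error near 0.15–0.20 at nominal 0.05. The test is
only asymptotically calibrated as $n_y \gg k$. Consequently BH-adjusted
$q$-values from this test do not control the false discovery rate at
their nominal level, and significance calls should be read as a
*ranking* device; transcriptome-wide summaries (`dv_classify`: fraction
of genes with positive $\Delta var$, median, skewness, Wilcoxon signed
rank) and the continuous statistic — which is calibrated — carry the
inferential weight. The statistic is kept in this form because it is the
established procedure this package implements; the limitation is a
property of the method, not of the implementation.

# Preprocessing

`quantile_normalize` forces all samples onto the reference distribution
given by row means of the column-sorted matrix; ties receive the mean of
the reference values their ranks span (the standard microarray
convention; `limma::normalizeQuantiles` is used as a tie-free oracle in
the tests). `correct_covariates` removes covariate effects by per-gene
OLS — age is *not* included, so the corrected matrix retains the age
signal for the grouped statistic. `summarize_probes` drops multi-gene
probes and averages same-gene probes; `filter_age` restricts to the adult
window with inclusive bounds.

# Pathways

`gsea_preranked` implements weighted preranked enrichment: genes are
sorted by decreasing score (ties broken by gene id for determinism), a
set's enrichment score is the signed extremum of the running sum that
adds $|s|/\sum_{hits}|s|$ at members and subtracts $1/(N - n_{hit})$
elsewhere; the extremum is found in $O(n_{hit})$ by evaluating the
running sum only at member positions. Nulls are random same-size gene
sets; NES divides by the mean |ES| of same-sign null scores and $p$ uses
the add-one permutation convention within the same-sign null, followed by
BH. `pathway_distribution` summarizes the per-set medians of any per-gene
score (e.g. $\Delta var$), reporting each median, the fraction of sets
with a strictly positive median, and the mean of medians. Set size
filters are applied after intersecting with the analyzed universe.

# Association checks

`mean_var_association` cross-tabulates the signs of each gene's mean
change (old minus young means) and its $\Delta var(IQR)$ and applies
Fisher's exact test; `fisher_2x2` computes the two-sided $p$ by direct
hypergeometric enumeration with the standard relative tolerance
$(1 + 10^{-7})$ for "as extreme" (cross-checked against
`stats::fisher.test`). `overlap_test` gives Jaccard plus Fisher on the
$2 \times 2$ membership table; `score_correlation` Spearman-correlates a
DV score with any external per-gene score on the shared genes.

`celltype_specific_genes` standardizes each gene across samples and calls
a gene specific to a cell type when its mean $z$ over that type's samples
exceeds 2. Note the arithmetic ceiling: if a type holds a fraction $f$ of
the samples, its mean $z$ cannot exceed $\sqrt{(1-f)/f}$, so the
threshold of 2 is only attainable for types comprising under a fifth of
the samples — appropriate for marker panels measured across many sorted
populations, not for a two-group design.

# Synthetic data

`simulate_dataset` draws ages uniformly on 20–80, by default with exact
quota counts 53/72/22 in the 20–40/40–60/60–80 bins at $n = 147$ (largest
remainder rounding for other sizes), plus sex, race, batch (19 levels),
PMI, RIN and pH covariates with configurable effect sizes. Gene means
follow the DE model with planted slopes; variance trends are planted as
$\sigma_j = \sigma_0 (1 + \gamma (a_j - 20)/60)$ (linear shape) or
$\sigma_j = \sigma_0 (1 + \gamma\, \mathbb{1}[a_j \ge 50])$ (step shape) —
with the step shape, $\gamma = 1$ exactly doubles the old-group SD, which
the acceptance script uses as an effect-size anchor
(`grouped_step_mean_dvar` $\approx 1$). All draws happen in a fixed
vectorized order from the single seed, so results do not depend on how
genes are later evaluated. The returned `truth` table carries the planted
slopes, $\gamma$s and labels for scoring recovery and false-discovery
proportions.

# Reproducibility

All stochastic functions accept an explicit `seed` and restore the
caller's RNG state. `scripts/acceptance.R --seed <int> --out <path>`
reruns the whole battery (calibration, effect-size recovery, FDP in a
mixture, DE slope recovery, transform concordance, pathway null) and
writes the computed quantities as JSON.
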