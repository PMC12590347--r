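---
title: "Deriving and applying minimal cytokine-activated mast-cell signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying minimal cytokine-activated mast-cell signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mastsig)
```

## The problem

Mast cells reshape their transcriptome when primed by the cytokine milieu of
their tissue — a T1/pro-inflammatory environment (IFN-γ), a T2/allergic one
(IL-4 + IL-13), an alarmin-rich one (IL-33), or a pro-fibrotic one (TGF-β).
`mastsig` implements a complete workflow for (i) deriving *minimal*
cytokine-activated gene signatures from a paired multi-condition bulk priming
experiment and (ii) using those signatures to detect cytokine priming in
bulk, pseudobulk and single-cell expression data. Because the workflow spans
several statistical machines, every stage has a matching synthetic-data
generator so that each claim the package makes is testable end to end
without any external dataset.

The pipeline, end to end:

1. **Differential expression** of each priming condition against the
   unstimulated control (negative-binomial Wald tests, median-of-ratios
   normalization, BH-FDR at 0.05).
2. **Venn partitioning** of the significant genes into condition-unique and
   shared sets; only condition-unique genes feed selection, so each
   signature gene carries an unambiguous class label.
3. **Multinomial elastic-net selection** (`alpha` = 0.5,
   `lambda` = 0.007976564, a stratified 70/30 split) reduces the unique DEGs
   to a minimal discriminative signature per condition, evaluated with exact
   classifier statistics and cross-validated by a small neural network; the
   weakest class (typically the unstimulated "signature") can be dropped.
4. **Application**: GSVA enrichment scores on bulk or pseudobulk profiles
   with moderated (empirical-Bayes) disease-vs-healthy comparisons; per-cell
   mean log-normalized signature scores with Wilcoxon cluster markers and
   Welch contrasts; pseudotime tertile phases with Fisher
   trajectory-utilization tests; and a cohort-level z-score statistic.

## Models and their assumptions

### Negative-binomial Wald differential expression

Counts for gene $g$ in sample $j$ are modelled as
$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g)$ with
$\mathrm{Var} = \mu + \alpha\mu^2$ and
$\log \mu_{gj} = x_j^\top \beta_g + \log s_j$, where $s_j$ are
median-of-ratios size factors and the design is `~ donor + condition` for
the paired four-donor experiment (`paired = FALSE` drops the donor terms).
Dispersion estimation is a deliberately simple empirical-Bayes workflow:

* a per-gene raw estimate solving the Pearson moment equation
  $\sum_j (y_{gj}-\hat\mu_{gj})^2/(\hat\mu_{gj}+\alpha\hat\mu_{gj}^2) = n-p$,
  with one dispersion-updated refit (approximately mean-unbiased even at the
  3 residual degrees of freedom of the paired design; genes underdispersed
  by chance get 0);
* a mean–dispersion trend $\exp(a_0 + a_1\log\bar\mu_g)$ fitted to binned
  means of the raw estimates (bin means keep zeros, so the fit targets the
  local mean dispersion without the log-scale Jensen bias; a weighted
  log-linear fit across ~20 quantile bins);
* linear precision-weighted shrinkage
  $\hat\alpha_g = (d\,\hat\alpha^{raw}_g + d_0\,\hat\alpha^{tr}_g)/(d+d_0)$
  with residual df $d$ and prior df $d_0 = 10$. Linear (not log-scale)
  shrinkage keeps genes whose raw estimate hit zero at a sane fraction of
  the trend instead of collapsing them.

The Wald statistic of the condition coefficient is referred to a
$t_{d+d_0}$ distribution: the moderated degrees of freedom acknowledge that
the shrunken dispersions are estimates, and on the package's null
simulations this choice is calibrated (rejection ≈ 0.045 at nominal 0.05)
where a standard-normal reference measured anti-conservative (≈ 0.065).
This is an intentional simplification of the full DESeq2 machinery — no
Cox–Reid adjustment, outlier replacement or independent filtering — and the
package's claims about it are calibration and recovery properties, not
bit-level equality with any specific tool. One known limitation is shared
with that method class: at $n = 4$ donors per arm the *middle* of the null
p-value distribution is mildly conservative (median null p ≈ 0.57) even
though the rejection tail is calibrated; the tests therefore bound the
sup-norm distance to uniformity (KS statistic < 0.1) rather than demand
strict uniformity.

"Bonferroni–Hochberg FDR" in this field's methods sections means the
Benjamini–Hochberg step-up procedure; that is what `bh_adjust()` applies,
with non-converged or all-zero genes excluded from the denominator.

### Signature selection and its evaluation

The multinomial elastic net minimizes the penalized deviance with mixing
$\alpha = 0.5$ and penalty $\lambda = 0.007976564$ (the workflow's fixed
operating point; `lambda = NULL` runs a 5-fold deviance-loss
cross-validation instead). Genes are standardized on the training split
only and the statistics are reused on the test split — this prevents
leakage. A gene enters the signature of the condition whose *unique-DEG
list* contains it; the elastic net only decides whether the gene is kept
(any class coefficient with $|\beta| > 10^{-8}$, the numerical floor of
coordinate-descent solutions). Class identity never comes from which
coefficient row is nonzero, because exclusivity is already fixed upstream.

Evaluation reproduces the exact small-sample statistics appropriate to a
5-sample test set: accuracy with its exact Clopper–Pearson interval
(`clopper_pearson(5, 5)` lower bound 0.4782), the exact binomial test of
accuracy against the no-information rate
(`exact_binomial_ge(5, 5, 0.2)` = 0.00032;
`exact_binomial_ge(9, 10, 0.2)` = 4.198e-06), Cohen's kappa
(0.875 for 9/10 correct on uniform 5-class margins), per-class
sensitivity/specificity, and multiclass AUCs. The Hand–Till M statistic on
class probabilities is the default multiclass AUC; binarized predictions
would also be computable, but probabilities retain strictly more
information. The validation network is a single-hidden-layer softmax
classifier (8 units, weight decay 0.01): its role is only to confirm that
the selected genes still separate the classes under a different inductive
bias, so a small deterministic net is preferable to anything tuned.

### The GSVA engine

`gsva_score()` is a self-contained implementation of gene set variation
analysis: per gene, a kernel-smoothed cumulative density across samples
(Gaussian kernel with bandwidth $s_g/4$ on log-scale input; a Poisson
kernel for raw counts; or the plain ECDF, which makes the whole pipeline
rank-only); per sample, genes are ranked by that statistic (ties broken by
gene order, making scores exactly reproducible) and folded into the
symmetric statistic $|N/2 - r|$; a weighted Kolmogorov–Smirnov random walk
accumulates $|stat|^\tau$ (normalized within the set) for set genes against
$1/(N-|S|)$ outside. The default score is the maximum positive deviation
plus the maximum negative deviation (`max_diff`), bounded in $[-1, 1]$; the
`two_sided_max` variant returns the deviation of largest magnitude. The
engine is verified against an independently coded brute-force oracle to
1e-10. Pseudobulk profiles are plain per-group count sums; groups under 10
cells are flagged (not dropped) because their scores are unstable.
Moderated group comparisons of the score matrix use limma's linear model +
empirical Bayes; with only 4–5 signatures the variance prior is weakly
estimated, and the function warns below 10 features rather than pretending
otherwise.

### Single-cell scores, phases and the cohort statistic

Per-cell scores are the mean *natural-log* normalized expression
(`log1p(count/total * 1e4)`) of each signature's genes — the single-cell
convention — while every bulk/pseudobulk stage uses log2 CPM; the two bases
are deliberate and documented at each interface. A disease-vs-healthy
"log2FC" of signature scores is reported as the *difference of group mean
scores*, since scores are already means of logged expression; a
ratio-of-means variant sits behind `logFC_mode = "ratio"`.

Pseudotime analytics: "natural binning" is read as 1-D Jenks/Fisher optimal
breaks (exact dynamic programming, deterministic); equal-width and
equal-count binning are selectable because the phrase is ambiguous in the
field. Tertile phases (early/mid/late) split each trajectory at the 1/3 and
2/3 pseudotime quantiles — by cell count, not range, with boundary ties
going to the earlier phase; a 10-cell uniform trajectory splits 4/3/3.
Trajectory utilization per disease is tested with two-sided Fisher exact
tests (all table probabilities ≤ the observed one), BH-adjusted across the
trajectory × disease grid; phase-level mean scores mask strata with fewer
than 5 cells (the threshold the workflow uses for display reliability;
exactly 5 is reported). The optional `centroid_mst_pseudotime()` is a
simplified convenience — an MST over cluster centroids with projected arc
positions — not a principal-curve method; real trajectory inference is
expected to come in as input.

The cohort statistic standardizes each signature gene's log2-CPM expression
across subjects ($z$-scores with the sample sd, computed across *all*
subjects rather than within groups — the unstated alternative — because the
statistic should measure between-group displacement on a common scale),
averages z per subject per signature, and compares groups with Welch
t-tests plus Spearman/OLS association between signatures.

## What the generators emulate — and what they do not

* `simulate_bulk_priming()`: 4 donors × 5 conditions, paired donor effects
  (log-normal, sd 0.25), NB counts with log-uniform dispersions in
  [0.01, 0.5], and planted truth: 10 condition-unique DEGs per cytokine and
  30 shared DEGs with |log2FC| in [2, 4]. The planted markers are strong
  (4- to 16-fold) on purpose: they represent the top condition-unique
  responders that a minimal-signature selector is supposed to find, and
  with 20 samples an L1-type selector cannot retain more than a few dozen
  genes, so a design planting hundreds of weak markers would make
  "recovery" meaningless rather than hard.
* `simulate_tissue_cells()`: per-disease trajectory-utilization
  probabilities, uniform pseudotime, clusters = tertile × trajectory (so
  phase analytics are exactly checkable), NB counts with Bernoulli dropout
  on top, and per-disease per-signature mean shifts on the log scale.
* `simulate_cohort()`: 20 vs 17 subjects with designated signatures
  elevated by a common log2 effect in the "high" group.

None of the generators attempt batch structure, ambient RNA, UMI chemistry,
gene–gene correlation, or realistic pseudotime geometry. Passing tests
therefore demonstrate that the *statistical machinery* is correct and
calibrated under its own assumptions — not that real tissue data satisfy
those assumptions.

## Numerical choices and degenerate inputs

* Dispersions are clamped to $[10^{-8}, 100]$; GLM linear predictors to
  $\pm 30$; IRLS converges on relative coefficient change $< 10^{-8}$ with
  50 iterations, and non-converged genes are flagged and excluded from the
  BH denominator rather than reported with untrustworthy p-values.
* Elastic-net nonzero threshold $|\beta| > 10^{-8}$.
* GSVA ties break by gene order; a set covering every gene (no out-of-set
  increment) yields NA with a warning, as does a set below `min_set_size`.
* All-zero genes, zero-total cells, constant genes (Wilcoxon p = 1,
  z-score 0), single-cluster z-scaling, sub-3-cell trajectories (all
  "early") and sub-`min_cells` phase strata all degrade to explicit NA +
  warning paths, never silent numbers.
* Every generator is bit-reproducible under its seed; splits, CV folds and
  network initialization take explicit seeds.

## Problem sizes used by the test-suite

Simulation-based checks run at deliberately modest sizes that still give
the relevant statistics room to behave asymptotically where needed: 2,000
genes for recovery studies (10,000 for the type-I calibration run), 20
seeds for selection recovery, 100 replicates for cohort power, and
enumeration oracles at N ≤ 200 (Fisher), ≤ 16 samples (Wilcoxon) and 6 × 4
(GSVA). These sizes are the package's own choices for reproducible
desk-scale verification.
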