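---
title: "Classifying fibroblast senescence states in PC space: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying fibroblast senescence states in PC space: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senpred)
```

## The problem

Cellular senescence — stable cell-cycle arrest reached at the Hayflick limit
and deepened by further time in culture — leaves a strong transcriptomic
signature in fibroblasts. `senpred` trains a classifier on single-cell RNA-seq
profiles of reference fibroblast populations labeled early-proliferative
(EP), early-senescent (ES) or deeply-senescent (DS), and then scores query
cells from other experiments or tissue atlases. The downstream quantity of
biological interest is a donor's *senescent-cell burden*: the percentage of
their fibroblasts classified DS, which in skin cohorts rises with donor age.

## Pipeline overview

1. **QC and normalization.** Per-cell metrics are total counts, detected
   genes, mitochondrial percentage (case-sensitive `MT-` prefix on gene
   symbols, configurable for non-human data) and
   `log10(n_genes)/log10(n_counts)`. Two presets ship: `default`
   (counts > 1000, genes > 400, mito <= 12%) and `integration`
   (counts > 500, 250 < genes < 7500, mito <= 5%, complexity < 0.8), the
   latter intended for merged whole-tissue donor datasets. Bound strictness
   follows the inequalities exactly: lower and upper bounds strict, the
   mitochondrial bound inclusive, so a cell at exactly 1000 counts is
   removed while one at exactly 12% mitochondrial content is kept.
   Normalization is counts-per-10K with natural-log `log1p`; zero-total cells
   are legal in QC (their mito percentage is defined as 0 and flagged) but an
   error in normalization, because QC must be computable before filtering.
2. **Feature space.** The top 2000 variable genes are chosen by standardized
   variance under a variance-stabilizing fit — loess (span 0.3, degree 2) of
   log10 variance on log10 mean, standardized values clipped at
   `sqrt(n_cells)`. For degenerate inputs with fewer than 50 variable genes
   the span falls back to 1 so the local regression remains estimable; the
   default path is unchanged. Selected genes are z-scored (clip 10) and
   decomposed by SVD. "All principal components" is operationalized as
   `min(50, n_cells - 1, n_genes)` components by default — a deliberate,
   configurable reading, since a PC count must be finite and 50 is the
   conventional ceiling in this field. PC signs are fixed by making the
   largest-magnitude loading of each component positive, so results are
   machine-independent.
3. **Clustering and markers** (exploration, not required for
   classification). A k-nearest-neighbor graph (k = 20 including self,
   Euclidean distance in PC space) is converted to shared-nearest-neighbor
   Jaccard weights, pruned below 1/15, and partitioned by Louvain at
   resolution 0.8; a resolution sweep (`sweep_resolution()`) replaces visual
   resolution-picking aids with a reported grid. Marker genes use the
   Wilcoxon rank-sum test on normalized values, screened at detection
   fraction > 0.25 (in cluster or rest) and |log2 FC| > 0.25 with
   pseudocount 1 on de-logged means, Bonferroni-adjusted over the genes
   tested per cluster.

## The MDA model

The classifier at the core is mixture discriminant analysis: class $j$ has
density
$$f_j(x) = \sum_{r=1}^{R_j} \pi_{jr}\, \mathcal{N}(x;\, \mu_{jr},\, \Sigma),$$
a mixture of $R_j$ Gaussian subclasses (default 3) sharing one pooled
covariance $\Sigma$ across all subclasses of all classes. Subclasses capture
within-state heterogeneity — senescent cultures are not homogeneous — while
the shared covariance keeps the parameter count low in PC space. Because
class labels are observed, EM runs only over the latent subclass
memberships: the E-step computes within-class responsibilities
$\gamma_{ijr} \propto \pi_{jr} \mathcal{N}(x_i; \mu_{jr}, \Sigma)$, the
M-step updates $\pi$, $\mu$ and the responsibility-weighted pooled
covariance. Numerical choices:

* $\Sigma$ is regularized as $\Sigma + \lambda I$ with
  $\lambda = 10^{-6} \cdot \mathrm{mean}(\mathrm{diag}\,\Sigma)$ — relative,
  because PC scores are approximately but not exactly white.
* Initialization is per-class k-means under a fixed seed (one subclass per
  cell when a class is as small as its subclass count, with the count reduced
  and a warning when smaller). This differs from the optimal-scoring/LVQ
  start of the classical implementation of this model family: the fitted
  family is identical, fitted parameters need not be bit-identical.
* Densities and posteriors are computed in log space with per-row max
  subtraction; argmax ties break by class order.
* Convergence is declared at relative log-likelihood change below `1e-6`;
  the trace is stored and is non-decreasing (asserted in tests).

With $R_j = 1$ the model collapses to linear discriminant analysis, which the
test suite exploits: posteriors must match an independently coded closed-form
LDA to `1e-6`.

## Training harness

Training splits are stratified (per-class proportions preserved to one cell)
and seeded. Model selection and reporting use stratified k-fold CV (default
5) *on the PC scores of the full training embedding* — the embedding itself
is not re-fit per fold, matching the reference-projection workflow this
package implements. Besides MDA, three one-vs-rest backends are available
with small seeded grids chosen by mean CV ROC-AUC: SVM-RBF (cost 0.25/0.5/1,
kernel width by the median pairwise-distance heuristic), KNN (k = 5/7/9,
posterior = neighbor vote fraction), and unpenalized binomial GLM. One-vs-rest
probabilities are renormalized to sum to 1. ROC-AUC uses the rank
(Mann–Whitney) formula and is cross-checked against an independent
implementation in the tests.

**Query projection** restricts the query to the training HVGs, scales with
the *training* mean/sd/clip, imputes genes missing from the query at the
training mean (scaled value 0), re-centers with the training centering
vector, and multiplies by the training loadings. More than 50% missing HVGs
is an error (configurable). Projection of the training matrix reproduces the
training scores to numerical precision. Batch harmonization between
reference and query is deliberately *not* applied by default — its effect on
this workflow is undocumented — but `project_query(align =)` provides the
insertion point for one.

**Assignment** uses a posterior rejection threshold of 0.55 (the
conventional default for reference-projection classifiers): a cell whose
maximum posterior is below it is labeled `unassigned`; at or above it, the
argmax class. `evaluate_classifier()` instead uses plain argmax so confusion
matrices are complete; because it is ambiguous whether published percentage
plots count unassigned cells, burden summaries report percentages both over
all cells and over assigned cells.

## Cohort analyses

`burden_by_donor()` joins predictions to metadata (validated one-to-one),
restricts to annotated fibroblasts (or any caller-supplied mask, for
datasets where fibroblast identity comes from marker inspection), and drops
donors with fewer than 100 fibroblasts — applied uniformly, configurable.
Unassigned cells stay in the denominator by default. `correlate_with_age()`
is the Pearson coefficient with the exact t-transform p-value on n − 2
degrees of freedom. Marker-panel correlation (default panel CDKN1A, CDKN2A,
IGFBP3, SERPINE1, IGF1, CXCL12, IL6, MMP3, TP53) masks constant genes as
undefined rather than forcing 0, and orders genes by Ward clustering;
`matrisome_profile()` takes per-condition medians of normalized expression,
drops genes with all-zero medians, and Ward-clusters conditions and genes.
All Ward clustering uses the squared-Euclidean "ward.D2" criterion; the
choice of Ward variant was open and is pinned here.

## The synthetic-data generator

`simulate_counts()` draws negative-binomial counts (dispersion 0.1; variance
$\mu + \phi\mu^2$) with log-normal gene base means (sd 1 on the log scale),
log-normal library sizes centered at 10,000 UMIs (log-sd 0.3), a 10-gene
`MT-` block scaled to 5% of counts in expectation, and 100 of 1000 genes
differential at |log2 FC| = 2 between EP and DS (half up, half down). ES is
modeled as a per-cell interpolation between the EP and DS programs:
coefficient $t \sim \mathcal{N}(0.5, 0.15)$ clamped to \[0, 1\], making ES a
heterogeneous bridge population — the feature that makes ES the
hardest class to classify, as observed in real data. Gene-level parameters
are drawn under a separate `program_seed` so that datasets sampled under
different seeds share the same biology and classifiers transfer between
them; the sampling `seed` controls everything cell-level.

`simulate_cohort()` draws 23 donors with ages uniform on 20–90 years and a
true DS fraction `clamp(0.05 + 0.004·age + N(0, 0.08), 0, 1)`, each donor
contributing 120–400 fibroblasts. These defaults were fixed by an a-priori
power calculation: with age sd ≈ 20 years the planted signal sd is ≈ 0.08,
giving a population age–burden correlation near 0.69, for which a two-sided
Pearson test at n = 23 donors has ≈ 96% power at α = 0.05 — high enough
that a 20-seed recovery experiment passes in ≥ 18 seeds with high
probability. A weaker planted correlation (≈ 0.5, closer to published skin
cohorts) would make such a repeated-recovery check fail by design at this
cohort size, so the generator plants the stronger trend and the observed
correlation magnitude is read as a property of the generator, not an
empirical estimate for real skin.

What the generator does *not* emulate: batch effects, ambient RNA, doublets,
zero-inflation beyond NB sampling, realistic gene-gene correlation
structure, or cell-type mixtures. Passing tests therefore demonstrate
correctness of the algorithms under a clean generative model, not expected
performance on real tissue.

## Problem sizes and determinism

The shipped tests run the full pipeline at moderate scale — two-class
training at 2000 cells × 500 genes, three-class at 1500 cells, cohort
recovery over 20 seeded cohorts of ~23 × 260 cells — sizes chosen so the
whole suite completes in a few minutes on one core while keeping every
statistical check well-powered. All randomness (splits, folds, k-means
initialization, Louvain tie-breaking, simulation) flows from explicit seed
arguments; repeated runs are bit-identical.

## Known limitations

* The EM fit is a local optimizer; different seeds can reach different
  subclass configurations (the class posteriors are typically stable even
  when subclass parameters are not).
* `glm` is unpenalized and will warn (suppressed) under perfect separation;
  its probabilities saturate but rankings remain usable.
* KNN posteriors are vote fractions over small k, hence coarse; with the
  0.55 threshold and k = 5, cells need 3 of 5 neighbors in one class.
* The marker Wilcoxon test is unpaired per cluster and ignores donor
  structure; for cohort data a pseudobulk approach would be more
  conservative.
* Query projection assumes the query was normalized under the same
  counts-per-10K natural-log contract as training.
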