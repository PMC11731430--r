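# senpred

Single-cell classification of fibroblast senescence state, and estimation of
donor-level senescent-cell burden.

Replicative senescence leaves a strong transcriptomic signature in human
dermal fibroblasts. `senpred` trains classifiers on single-cell RNA-seq
reference data labeled **EP** (early-proliferative), **ES** (early-senescent,
cells at the Hayflick limit) and **DS** (deeply-senescent, arrested cells
kept weeks beyond it), then projects query cells into the trained
principal-component space and scores them. Summed per donor, DS calls give a
*senescent-cell burden* whose correlation with donor age is the downstream
readout for tissue cohorts.

The core model is **mixture discriminant analysis (MDA)**: each class *j* is
a Gaussian subclass mixture with a covariance pooled across all subclasses,

f_j(x) = Σ_r π_jr · N(x; μ_jr, Σ),

fit by EM over the latent subclass memberships on PC scores, with
P(j | x) ∝ prior_j · f_j(x) and an `unassigned` call when the maximum
posterior falls below a rejection threshold (default 0.55). SVM-RBF, KNN and
binomial GLM backends are available through the same harness (stratified
5-fold CV with ROC-AUC / sensitivity / specificity reporting). Around the
model sit 10x-style Matrix Market IO, per-cell QC presets, counts-per-10K
log-normalization, variance-stabilized HVG selection, PCA, SNN-Louvain
clustering, Wilcoxon marker testing, marker-panel and matrisome Ward
clustering, and a deterministic negative-binomial simulator (EP/ES/DS
programs with ES as a jittered interpolation between EP and DS, plus an
age-structured donor cohort) so the full pipeline runs with no downloads.
The methods vignette (`vignettes/senpred-methods.Rmd`) documents every model
and default.

## Worked example

```r
library(senpred)

cfg <- simulation_config(seed = 1)          # 1000 genes, 1000 EP + 1000 DS cells
sim <- simulate_counts(cfg)
qc  <- compute_qc(sim$counts)
cm  <- filter_cells(sim$counts, qc, qc_thresholds("default"))
#> filter_cells: 2000 of 2000 cells retained (preset: default)
nm  <- log_normalize(cm)

labels <- sim$labels[colnames(cm)]
split  <- stratified_split(labels, test_fraction = 0.2, seed = 1)
tc <- train_classifier(nm[, split$train], labels[split$train],
                       method = "mda", seed = 1)
print(tc)
#> senpred classifier (mda): classes EP/DS, 1000 genes, 50 PCs
#>   mean CV:  roc_auc=1, sensitivity=1, specificity=1, accuracy=1

ev <- evaluate_classifier(tc, nm[, split$test], labels[split$test])
print(ev)
#> senpred evaluation on 400 cells: accuracy 1 , macro ROC-AUC 1
#>      predicted
#> truth  EP  DS
#>    EP 200   0
#>    DS   0 200
```

On this clean synthetic reference the held-out confusion matrix is exactly
diagonal: the EP and DS programs differ in 100 genes at |log2 FC| = 2, which
is far more separation than the classifier needs. Classifying an independent
simulated donor cohort and correlating burden with age:

```r
coh  <- simulate_cohort(simulation_config(seed = 2))
pred <- classify_cells(tc, log_normalize(coh$counts))
cs   <- burden_by_donor(pred, coh$metadata, min_fibroblasts = 100)
head(cs[, c("donor_id", "age", "n_fibroblasts", "pct_DS", "pct_unassigned")], 3)
#>   donor_id      age n_fibroblasts   pct_DS pct_unassigned
#> 1      D01 32.94176           138 12.31884              0
#> 2      D02 69.16618           197 31.97970              0
#> 3      D03 60.13284           207 29.46860              0
correlate_with_age(cs, field = "pct_DS")
#> pct_DS vs age over 23 donors: Pearson r = 0.588, p = 0.00317
```

Each donor's `pct_DS` is the percentage of their fibroblasts classified DS
(unassigned cells counted in the denominator; donors under 100 fibroblasts
dropped), and the planted positive age trend of the cohort generator is
recovered as a significant positive Pearson correlation.

A thin CLI over the same functions ships in `inst/cli/senpred`
(`simulate`, `qc`, `train`, `predict`, `evaluate`, `cohort` subcommands).

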