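---
title: "Biomarker signature discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomarker signature discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sigselect)
```

# The procedure

`sigselect` treats biomarker discovery as a *combined* model-and-feature
search. Given sample × feature tables and an outcome column, the pipeline
runs:

1. inner join of all input tables on the sample identifier, with exactly
   one table carrying the outcome;
2. a stratified train/test split (default 2/3 train), or a user-supplied
   test file;
3. imputation of missing cells from training-set statistics only;
4. univariate feature ranking and dimension reduction;
5. for every classifier × criterion, four stepwise wrapper searches plus
   top-*k* baselines, each scored by k-fold cross-validation;
6. multi-procedure evaluation of every candidate model;
7. stability-gated best-model selection, optional ensemble voting, and
   correlated-feature signature enrichment.

The result object behaves like a fitted model (`print`, `summary`,
`predict`, `coef`, `plot`), and every candidate is checkpointed to an
append-only CSV registry so interrupted runs can be resumed
(`sig_resume()`).

## Assumptions

Input tables are assumed clean and consistent: upstream normalisation,
batch correction and unit harmonisation are out of scope. Sample and
feature names must be unique. Classification outcomes are nominal,
regression outcomes numeric; classes may be unbalanced — all default
metrics (MCC, BER, prevalence-weighted one-vs-rest sensitivity /
specificity / AUC / AUPRC) are chosen to remain meaningful under
imbalance.

# Feature ranking

Classification uses Information Gain in bits, `IG(A) = H(Y) − H(Y|A)`.
Numeric features are first discretised by supervised entropy minimisation
with the minimum-description-length stopping rule: a binary split is
accepted only when its gain exceeds `(log2(N−1) + Δ)/N`, recursively. A
feature whose discretisation collapses to a single interval carries no
detectable class information and scores exactly 0. We deliberately do
**not** fall back to unsupervised equal-frequency binning in that case: a
10-bin fallback would award every pure-noise feature a spurious gain of
roughly `(bins−1)(classes−1)/(2 N ln 2)` ≈ 0.04 bits at N = 150, defeating
both the 0.01 relevance threshold and the permutation-null behaviour the
package tests (permuted labels must drive the 95th percentile of merits
below the threshold).

Regression uses RReliefF: instances are sampled (default
`min(n, 250)` iterations, seeded), their `k = 10` nearest neighbours found
under range-normalised Manhattan distance, and each feature is credited
when its differences track outcome differences. Neighbour contributions
are uniformly weighted; weights lie in [−1, 1] and are kept signed, the
ranking ordering on `|merit|`. ReliefF for classification (hit/miss
formulation with prior-weighted misses) is also available, but the default
binding is Information Gain ↔ classification, ReliefF ↔ regression.
Because ReliefF's neighbourhoods are computed over *all* features, its
power to credit a relevant feature degrades as irrelevant dimensions swamp
the distance; the shipped regression fixtures therefore sit at moderate
dimensionality (p ≈ 30 at n = 150), and users with p ≫ n regression
tables should expect the ranking to need stronger per-feature signal than
Information Gain does for classification.

Features with `|merit| ≤ 0.01` (configurable) are dropped; at most the
`cap = 1000` best are kept, ties broken by column order for determinism.
An empty ranking aborts the run — with no relevant feature there is
nothing to model.

# Stepwise subset search

All four searches walk the merit-ranked list (inverted for the backward
variants, which start from the *worst* ranked feature) and tentatively add
each feature, evaluating the subset by 10-fold CV on the optimisation
criterion. The criterion starts from a worst-score sentinel (0 for
maximised criteria, 1000 for minimised ones). Two reading decisions in the
published loop needed fixing in code:

* **Ties reject.** A feature is kept only on *strict* improvement. Equally
  predictive features are therefore retained by order of appearance —
  deterministic, and consistent with "kept if the model improves".
* **The post-elimination score carries forward.** In the elimination
  variants (FSSBSE, BSSFSE) each acceptance triggers a backward scan over
  the previously kept features (from the one before the last kept back to
  the first); a removal is kept when it strictly improves the criterion.
  The improved score becomes the bar for subsequent additions; leaving the
  pre-elimination score in place would readmit features that no longer
  help and break the monotonicity of accepted scores.

A run in which no feature is ever accepted returns a flagged
single-feature candidate (the best-ranked feature) rather than an empty
signature, which would break every downstream contract.

Top-*k* candidates (defaults k ∈ {1, 5, 10, 15, 20, 25, 30, 40, 50, 75,
100}) are built once per classifier under the first configured criterion;
per-criterion top-*k* is available via `topk_per_criterion` since the
published loop structure leaves the placement ambiguous.

# Evaluation

Each candidate is evaluated by:

* 10-fold CV (stratified folds; metric vectors averaged over folds),
* leave-one-out CV (pooled held-out predictions; skipped with a warning
  above `loocv_limit = 500` instances — an engineering guard, as n² fits
  get expensive),
* holdout on the reserved test set,
* repeated holdout (default 100 repeats, 1/3 held out, stratified,
  without replacement),
* out-of-bag bootstrap (default 100 repeats; each repeat trains on an
  n-sized resample with replacement and tests on the out-of-bag
  instances — the only statistically defensible reading, since
  resubstitution on the resample would be optimistic by construction),
* the 0.632+ estimator in the Efron–Tibshirani formulation:
  `γ` is the no-information error from the marginal truth × prediction
  distributions, the bootstrap error is clipped to `γ`, the relative
  overfitting ratio `R = (err_boot − err_resub)/(γ − err_resub)` is
  clipped to [0, 1] (0 when `γ ≤ err_resub`), `w = 0.632/(1 − 0.368 R)`,
  and the estimate is `(1−w)·err_resub + w·err_boot`. The reported *bias*
  (estimate − resubstitution error) tends to 0 for honest models and
  grows when a model memorises noise. Classification uses 0/1 loss;
  regression uses squared error.

The *stability summary* is the mean and population standard deviation of
MCC and BER (CC and RMSE for regression) across the procedures that ran.
Best-model selection takes the candidate with the best summary average
subject to `sd < 0.1`; if nothing passes the gate the smallest-sd
candidate is returned with a prominent warning. For regression runs the
default stability key switches to `avg_cc`. Alternative keys
(`test_mcc`, `train_test_bs_mcc`) are available for users who prefer the
holdout or merged-data bootstrap view.

# Ensembles and correlated features

Ensemble members are picked manually by identifier or by a metric rule
truncated to `max_models`. The published default rule prints as "average
MCC lower than 0.6"; read literally that admits only the *weak* models, so
the implementation defaults to the quality-filter direction (at or above
0.6) while keeping the direction configurable (`rule_direction = "le"`
restores the literal reading). Probability combination follows the stated
arithmetic; two numerical guards are ours: the product rule floors
probabilities at 1e−9 before renormalising (otherwise one member vetoes a
class outright), and majority ties go to the class with the highest
average probability.

Correlated-feature enrichment searches the *original*, pre-reduction
dataset, so redundant biomarkers discarded by the relevance threshold or
the 1000-feature cap are recovered: any feature with `|Pearson r|` or
`|Spearman ρ| ≥ 0.95` of a signature feature (the "almost correlated"
band), plus any ranked feature whose merit lies within 0.01 of a signature
feature's (the same scale as the relevance threshold, since the published
method gives no number for "same predictive power"). Nominal signature
features fall back to Spearman on rank-encoded values.

# Determinism and concurrency

Every stochastic step is seeded: splits, folds, resampling, ReliefF
sampling, and stochastic learners (random forest, neural nets) via an
isolated RNG that never touches the session's `.Random.seed`. Each search
task derives its own 31-bit seed by stable string hashing of
(classifier id, criterion, method, k) combined with the master seed, so
the task outcome is independent of execution order and the registry CSV is
byte-identical for any concurrency degree (`cores`). The stored
`criterion_score` of every candidate is reproducible by re-running the
fold CV with the stored seed.

# The synthetic generator

`generate_classification_data()` emulates the target data regime:
p ≫ n tables with unbalanced classes (default 150 samples × 1000
features, 60/40), planted informative features as class-conditional
Gaussians shifted by `effect_size` pooled SDs (default 1.5), exact
duplicate columns, injectable missingness, and optional column-wise
splitting into several source tables sharing sample identifiers.
`generate_regression_data()` plants a linear signal at a chosen
signal-to-noise ratio (default 3). `generate_xor_fixture()` constructs
the stress case for backward elimination: two features that separate the
classes only jointly plus a weak noisy feature that helps alone but
degrades the pair — forward selection keeps it, the elimination pass
removes it.

The generator models independent Gaussian features with mean shifts only.
It does **not** emulate realistic microarray noise, feature correlation
structure beyond exact duplicates, batch effects, or heavy-tailed
intensities; passing tests demonstrate the machinery recovers plantable
univariate signal and controls leakage, not that any particular real
dataset will yield a stable signature.

# Problem sizes in the shipped tests

The test-suite experiments use the generator's default study conditions
(n = 150, p = 1000, 10 informative at 1.5 SD, 60/40 classes, seeds 1–5
for signal; 0 informative, seeds 1–20 for null) with a deliberately small
classifier panel (nearest-neighbour, LDA, naive Bayes), the MCC criterion,
FSS/FSSBSE searches and 50 resampling repeats — the search space scales
with the panel, and this configuration keeps a full five-seed experiment
in a few minutes while exercising every stage. The stepwise trace
equivalence check runs all four methods against an independently coded
reference on twenty seeded n = 60, p = 10 fixtures.

One empirical point deserves emphasis: on *pure-noise* data the wrapper
search still inflates every train-side resampling metric, because the
subset was chosen to optimise exactly that kind of score — individual
null runs reach best-model average MCC of 0.3–0.4 and only the untouched
holdout stays near zero. This is selection optimism, not leakage (the
leakage tests corrupt the test set and observe bit-identical train-side
metrics). The 0.632+ bias is the designed detector: it sits an order of
magnitude higher on noise models (≈ 0.1–0.2) than on planted-signal
models (≈ 0.01).

# Known limitations

* Wrapper searches evaluate thousands of CV fits; the full default panel
  on a large table is an hours-scale computation. Restrict the panel, the
  criteria or the methods for interactive use.
* The classifier panel is a curated registry of standard R learners, not
  a reproduction of any particular toolkit's 80-configuration panel; it
  is user-extensible via `classifier_spec()`.
* AUC/AUPRC need probability scores; learners without calibrated
  probabilities report rank-based estimates of whatever scores they
  expose.
* Gene-set enrichment of discovered signatures is out of scope; export
  the signature subset (`export_signature_subset()`) to external tools.
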