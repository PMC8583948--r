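---
title: "Consensus multi-omics integration: methods and design notes"
author: "integromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus multi-omics integration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(integromics)
```

# The problem

Small biofluid case–control studies increasingly measure two omics layers
on (mostly) the same subjects — e.g. TMT reporter-ion protein abundances
and LC-MS metabolite peak intensities in cerebrospinal fluid — and ask
which few features jointly discriminate cases from controls. With 13–15
subjects and hundreds of features, any single selection algorithm overfits
badly. The strategy implemented here screens each layer for differential
abundance first, integrates only the significant features, runs two
different selection algorithms, and keeps only features that at least two
of the three resulting models agree on, before a final classifier is
evaluated on held-out samples.

# Per-layer differential screen

Each layer is a feature × sample matrix of non-negative intensities with a
two-level group factor (`OmicsLayer`, a `SummarizedExperiment`). The
screen (`runDifferential()`) applies, in order:

1. **Missingness filter.** Features missing in more than `maxMissing`
   (default 50%) of all samples are excluded. Missingness in these data is
   predominantly feature-level (a compound not measurable in most
   samples), which is exactly what this filter targets; surviving features
   are analysed complete-case — imputation is deferred to the integration
   stage, where it can be learned on training samples only.
2. **Dixon outlier removal.** Within each group independently, the most
   extreme value of each feature is tested with Dixon's gap-to-range ratio
   (variant r10/r11/r21/r22 switched on the sample size as is conventional)
   and blanked if p < `alphaOutlier` (default 0.05). The test is run in a
   single pass — at most one removal per feature per group — because
   Dixon's is a single-outlier test and iterating it inflates removals.
   Features where the test is inapplicable (n < 3, all values equal) are
   left untouched.
3. **Mann–Whitney U test,** two-sided. The exact permutation null is used
   when both groups have ≤ 8 observations and no ties; otherwise the
   normal approximation with mid-ranks, tie correction and continuity
   correction. At the design sizes here (6 vs 9 before removals) the
   approximation is in effect for the protein layer and the exact test for
   the metabolite layer (6 vs 7).
4. **Benjamini–Hochberg adjustment** across all tested features of the
   layer; `significant` means adjusted p < `fdr` (default 0.05).
5. **Fold change** `log2(mean(case)/mean(control))` on the values that
   survived removal; undefined (zero-mean) ratios give `NA`.

An optional feature→gene map (`collapseByGene()`) reduces multiple protein
features of one gene to the representative with the smallest adjusted p —
the natural reading of "significant proteins related to unique genes" when
no explicit collapsing rule is available.

## A power floor worth knowing about

The approximate two-sided Mann–Whitney p at 6 vs 9 cannot fall below
`2·Φ((0.5 − 27)/√72) ≈ 1.79e-3` (U = 0). Benjamini–Hochberg with m tested
features and k true effects at their floor therefore requires
`1.79e-3 · m / k < 0.05`. With 4 planted effects this caps the feature
space near m ≈ 110: a 200-feature layer carrying only 4 genuine effects
can never declare them significant at FDR 0.05, *regardless of effect
size*. This is a property of rank tests at these group sizes, not an
implementation artefact; it shapes the choice of simulation scenarios
below.

# Integration

`integrateLayers()` merges the significant features of both layers over
the samples present in both (metabolite intensities natural-log
transformed first — the base is immaterial because standardization
follows; zeros become missing), then:

- **Split.** 70:30 stratified train/test split with the training size
  rounded half-down, so 13 samples give 9 train / 4 test. Stratification
  is imposed although the underlying procedure says only "randomly
  divided": with a 4-sample test set an unstratified split has an
  appreciable chance of a single-class test set, making the confusion
  matrix degenerate.
- **Scaling.** Per-feature mean/SD (n − 1 denominator) estimated on the
  training rows only and applied to both partitions; constant features
  are centred only and flagged.
- **Imputation.** K-nearest-neighbour (default k = 5, truncated to the
  available donors): a missing cell is filled with the mean of that
  feature over the k nearest samples (Euclidean distance on mutually
  observed features, normalised by the number of shared features) that
  observe it. Test samples draw donors from the training partition only,
  so no information flows between test samples or from test to
  preprocessing. A feature observed in no donor falls back to the scaled
  mean 0 and is flagged.

# Selection routes

All three routes ride on elastic-net logistic regression
(`fitElasticNet()`, glmnet coordinate descent under the hood): penalty
`λ[α·Σ|βj| + (1−α)/2·Σβj²]`, α over `{0.1, …, 1.0}` and λ log-spaced over
`[1e-4, 10]·λ_max` (λ_max = the smallest penalty that zeroes all lasso
coefficients on the data at hand); the (α, λ) pair maximising mean
cross-validated accuracy at threshold 0.5 wins, with ties resolved toward
the sparser model (larger λ, then larger α). Nominal 10-fold, 5-repeat
cross-validation is requested, but with 9 training samples a class is
always smaller than 10 folds, so the implementation substitutes
leave-one-out — deterministic, hence one effective repeat — and records
the substitution on the model (`looUsed`). Feature importance is the
absolute coefficient (inputs are standardized, so magnitudes are
comparable), ties broken lexicographically.

- **RFE** (`rfe()`): outer resampling (same fold policy); per resample an
  elastic net is fit on all features and ranked *once*, then each
  candidate subset size is refit at the resample's chosen hyperparameters
  and scored on the held-out samples. Ranking once per resample rather
  than re-ranking after every elimination matches common practice and
  keeps the cost linear in the number of sizes. Each candidate size yields
  a `SelectionModel` whose selected set is the top of the full-training
  ranking, refit with fresh hyperparameter tuning.
- **mRMR** (`mrmr()`): greedy forward selection with the difference (MID)
  criterion. Relevance and redundancy both use the Gaussian
  mutual-information surrogate `−½·ln(1−ρ²)` — point-biserial ρ against
  the binary label for relevance, Pearson ρ against already-selected
  features for redundancy — with ρ clamped to |ρ| ≤ 1 − 1e-12. Constant
  features carry zero relevance and can never precede an informative one.
  The top-k selection (`mrmrSelection()`) is refit with an elastic net so
  that its test-set evaluation is commensurate with the RFE route.

# Consensus and final model

`consensusFeatures()` keeps features selected by at least `minOccurrence`
(default 2) of the source models — with RFE-7, RFE-9 and mRMR-30 this is
the 2-of-3 rule; `minOccurrence = 1` is the union and
`minOccurrence = #models` the intersection. The final elastic net
(`fitFinal()`) is re-tuned on the consensus features (hyperparameters are
not inherited — the conservative reading of "building a final model") and
evaluated on the untouched test partition as a confusion matrix with
`case` as the positive class and probability ≥ 0.5 predicting `case`.

`runPipeline()` chains all stages; every stage seed derives
deterministically from one master seed, and `resultToList()` /
`writeResults()` serialize the complete outcome, so reruns with equal
seeds are reproducible bit for bit. When a cohort yields fewer integrated
features than the nominal subset sizes (strong-signal simulations often
integrate exactly the planted features), the candidate sizes are clamped
to the feature count — the direct calls `rfe()`/`mrmr()` still reject
oversizes — and an empty consensus falls back to the union of selections
with a warning rather than aborting.

# The synthetic cohort generator

`generateCohort()` emulates the study design the package targets: 6/9
(protein) and 6/7 (metabolite) control/case samples with shared ids for
the 13 overlapping subjects, ~200 protein and ~80 metabolite features,
log-normal intensities `exp(log baseline + planted_log2fc·ln 2·I[case] +
N(0, noiseSdLog))`, planted effects drawn uniformly from −3.8…2.5 log2
units (the span of reported fold changes) and applied to the case group
only (matching the one-directional case-over-control fold-change
convention), a configurable share of non-planted features blanked in
⌊n/2⌋+1 samples (the >50% regime the missingness filter targets), and
sporadic single-sample ×10 spikes (the contamination Dixon's test is
built for). Defaults: `noiseSdLog = 0.5` (moderate biological plus
technical variation on the natural-log scale), 15% high-missingness
features, 5% spike rate, 30 + 10 planted features.

What it does **not** emulate: batch/run-order effects, TMT channel
interference or ratio compression, correlated feature blocks, value-level
missingness-not-at-random, or annotation ambiguity. Passing the recovery
simulations therefore demonstrates internal correctness of the chain —
not that real cerebrospinal-fluid data of this size would yield a stable
panel.

## Simulation scenarios used by the tests

- **Null screen** (type-I control): 20 cohorts at the study-mirror scale
  (200 protein features, no planted effects); the BH screen is expected
  to return essentially zero discoveries in total. The discreteness of
  the rank test makes this very stable.
- **Recovery** (end-to-end): 20 cohorts with 6 planted features (4
  proteins, 2 metabolites) at log2FC in [2, 2.5] and `noiseSdLog = 0.2`,
  on a screening-panel-sized feature space of 60 proteins + 30
  metabolites with 10% high-missingness features. The panel size follows
  directly from the power floor derived above (m ⪅ 110 at k = 4); it
  represents a targeted screen rather than the full discovery layer. The
  consensus is expected to contain ≥ 5 of the 6 planted features in at
  least 80% of runs with mean held-out accuracy ≥ 0.9.

These sizes also keep the complete test suite and the acceptance script
within a few minutes on a single core.

# Numerical choices

- **Dixon p-values** are taken from a Monte-Carlo tabulation of the null
  distribution of the two-sided statistic max(r_low, r_high) under normal
  sampling — 40,000 draws per sample size, fixed internal seed, cached
  per session, caller RNG state untouched. Classical printed tables cover
  only a handful of α levels and require interpolation; the Monte-Carlo
  table gives the same decisions at α = 0.05 with finer resolution and is
  fully deterministic. The candidate is min or max by the larger ratio,
  ties toward the max.
- **Degenerate Dixon denominators** (possible under heavy ties) yield a
  zero ratio — no evidence — rather than NaN.
- **Pathway coverage** rounds half *up* to two decimals
  (`floor(x·100 + 0.5)/100` with an epsilon guard), matching how printed
  coverage tables are rounded; base R's `round()` is half-even and would
  disagree on exact .005 boundaries.
- **Split arithmetic** rounds the training size half-down
  (`ceiling(r·n − 0.5)`), which is what makes 13 × 0.7 → 9.
- **glmnet specifics**: `standardize = FALSE` (the pipeline standardizes
  explicitly, keeping |coefficient| a valid importance), convergence
  threshold 1e-12 for final fits, and coefficients read directly off the
  fitted λ path (the requested λ is always a path member) instead of
  interpolating. λ = 0 with a decreasing warm-start path reproduces the
  unpenalized logistic fit to ~1e-5, which the tests pin against a base
  `glm` IRLS oracle. Single-feature fits pad an all-zero column (glmnet
  requires two); the pad can never acquire a coefficient and is dropped.
- **Class imbalance at the 0.5 threshold**: probability exactly 0.5
  predicts `case`; an intercept-only model on a balanced test set scores
  exactly 0.5 either way.

# Known limitations

- The Mann–Whitney power floor above means sparse signals in wide layers
  are invisible at these group sizes; widening the cohort, not the code,
  is the remedy.
- Dixon removal assumes approximate normality within feature × group; on
  strongly skewed raw intensities it removes legitimate tail values more
  often than its nominal level suggests.
- mRMR's mutual-information surrogate is exact only for Gaussian pairs;
  heavily non-linear dependence is under-weighted.
- With 9 training samples, leave-one-out accuracy is a high-variance
  model-selection criterion; the chosen (α, λ) can move with a single
  sample. Reported CV accuracies should be read as descriptive, not as
  unbiased performance estimates.
- The pathway module deliberately computes coverage only; enrichment
  p-values require a defensible background set that membership lists
  alone do not provide.
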