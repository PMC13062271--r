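---
title: "Tissue-specific anticancer peptide classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-specific anticancer peptide classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissueACP)
```

## The problem and the model

Anticancer peptides (ACPs) are short, typically cationic and amphipathic
sequences that lyse tumour cells. Activity is tissue-dependent: a peptide
potent against breast carcinoma lines may be inert against glioma lines.
`tissueACP` models tissue specificity as **nine one-versus-rest binary
classification tasks**, one per tissue in
`TISSUES` (`r paste(TISSUES, collapse = ", ")`).

The unit of analysis is a **(sequence, tissue) entry**: a peptide annotated
against two tissues contributes two entries and is a positive in two tasks.
For tissue $t$, every curated entry is labelled $y = 1$ if its tissue is
$t$ and $y = 0$ otherwise. This per-entry labelling means the negative set
for one tissue contains peptides active against *other* tissues — the task
is discrimination between tissues, not ACP-versus-random.

### Assumptions

- Activity annotations from source databases are trustworthy after keyword
  normalisation; entries whose free-text annotation matches zero or more
  than one tissue keyword are rejected, not guessed.
- Sequence composition (order-light statistics up to dipeptides plus
  λ = 3 sequence-order correlations) carries the tissue signal. No
  structural or 3D information is used.
- Identical sequences are correlated observations regardless of tissue
  label, so evaluation must be grouped by sequence.

## Curation pipeline

`curate_entries()` applies, in order:

1. **Sequence cleaning** (`clean_sequence()`): uppercase; reject any
   character outside the 20 standard amino-acid letters (no B, J, O, U, X,
   Z, gaps, or whitespace). Idempotent.
2. **Length filter** (`filter_by_length()`): keep $10 \le L \le 100$,
   inclusive at both bounds.
3. **Tissue assignment** (`assign_tissue()`): case-insensitive fixed
   substring matching against a curated keyword dictionary
   (`inst/extdata/tissue_keywords.yaml`) of cancer-type terms and cell-line
   names. Exactly one tissue match is required; otherwise the entry is
   logged `ambiguous` or `unmatched`.
4. **Activity standardisation** (`standardize_activity()`): molar IC50
   units (nM, µM, mM, M) are converted to µM; mass-per-volume units cannot
   be converted without molecular weight and yield `NA`; non-positive
   values are rejected.
5. **Deduplication** (`merge_and_deduplicate()`): one record per
   (sequence, tissue) pair. Sources are unioned; conflicting IC50 values
   resolve to the **minimum** (the most potent measurement), a deliberate
   optimistic convention recorded per conflict in an attribute. The same
   sequence under different tissues is *not* a duplicate.

Every rejection is logged with its reason, so curation is auditable.

## The 473-dimensional descriptor

`encode_peptide()` concatenates four blocks (fixed order, fixed names,
`feature_schema()` is the single source of truth):

| Block | Dim | Definition |
|---|---|---|
| AAC | 20 | residue counts / $N$; sums to 1 |
| DPC | 400 | overlapping dipeptide counts / $(N-1)$, row-major AA…YY; sums to 1 |
| PCP | 30 | 20 residue-group fractions $P_g/N$ + 10 global properties |
| PseAAC | 23 | Chou type-1, $\lambda = 3$, $w = 0.05$; sums to 1 |

PCP details: the 20 groups (positive, negative, charged, polar, hydrophobic,
aromatic, aliphatic, tiny/small/large, Chou–Fasman helix/sheet/turn formers,
etc.) live in `inst/extdata/residue_groups.yaml`. The 10 extras include
**net charge left unnormalised** (length itself is informative; dividing by
$N$ would conflate charge density with charge) and mean raw hydrophobicity.

PseAAC details: sequence-order factors
$\theta_k = \frac{1}{N-k}\sum_i \Theta(R_i, R_{i+k})$ with
$\Theta$ the mean squared difference of three standardized property scales
(Chou's hydrophobicity, hydrophilicity, side-chain mass;
`inst/extdata/property_scales.csv`, standardized to mean 0 / sd 1 over the
20 residues). The joint denominator $\sum_a f_a + w\sum_k \theta_k$
normalizes all 23 components to sum 1 (Chou's convention, the default
`mode = "chou"`); `mode = "raw"` exposes the unnormalised $f$ and
$w\theta$ components for users who prefer blocks that do not couple.

Valid input length is 10–100, matching curation, so $N - \lambda \ge 7$
and all $\theta_k$ are well defined.

## Group-aware splitting

`group_train_test_split()` and `group_kfold()` operate on **sorted unique
sequences** (order-invariant), permute them with the given seed, and assign
whole groups to partitions (test size `round(fraction × n_groups)`; k-fold
deals groups round-robin). If a draw leaves either partition without both
classes, it redraws with a derived seed, up to 25 attempts, then errors —
it never silently returns a degenerate split. Because grouping is by
sequence, a peptide duplicated across tissues can never appear on both
sides of a split.

## Classifier families and tuning

`acp_train(x, y, family, params, class_weighting, seed)` returns an
`acp_model` S3 object (with `print`, `summary`, `predict` methods) for the
five families in `MODEL_FAMILIES`. Implementation notes:

- **Standardisation**: SVM, logistic regression, and KNN standardize
  features using training-set moments only; constant columns are centred
  but not rescaled. Tree families use raw features.
- **Class weighting** (default `"balanced"`): $w_i = n / (2\,n_{y_i})$,
  mean 1. For xgboost the default is instead positive-class scaling,
  `scale_pos_weight = n_{neg}/n_{pos}`.
- **svm_linear**: `e1071::svm`, linear kernel, Platt-scaled probabilities.
- **random_forest**: `ranger` with impurity importance;
  `mtry = floor(sqrt(473)) = 21` (fixed, not tuned).
- **logistic_regression**: `glmnet`; the grid's `C` maps to
  `lambda = 1/(C·n)`, penalty `l1`/`l2` maps to `alpha` 1/0. The grid's
  `solver` axis is carried as an annotation only — `glmnet` has one
  optimiser — so tuning explores it but it cannot change the fit, and the
  incompatible (l1, lbfgs) pair is pruned from enumeration.
- **knn**: implemented in-package (~30 lines) because no installed package
  exposes both the metric axis (manhattan/euclidean) and the weight axis
  (uniform/distance). Zero distances get the neighbour's full weight.
- **xgboost**: `xgb.train`, `tree_method = "hist"`, `nthread = 1` for
  determinism.

### Search spaces (defaults in bold)

| Family | Grid | Configs |
|---|---|---|
| svm_linear | C ∈ {0.001, 0.01, **0.1**, 1, 10} | 5 |
| random_forest | trees {10, 50, **100**, 200} × depth {2, 3, 5, 7, **10**} × leaf {**5**, 10, 20} | 60 |
| logistic_regression | C {0.001, 0.01, 0.1, **1**, 10} × penalty {l1, **l2**} × solver {**lbfgs**, liblinear, saga}, l1+lbfgs pruned | 25 |
| knn | k {3, **5**, 7, 9, 11} × weights {**uniform**, distance} × metric {manhattan, **euclidean**} | 20 |
| xgboost | lr {0.01, 0.05, **0.1**, 0.3} × depth {3, **5**, 7} × trees {50, **100**, 200} × subsample {0.8, **1**} × colsample {0.8, **1**} | 144 |

`tune_model()` runs a randomized search (`n_draws = 50` by default;
exhaustive when the grid is smaller) with group-aware `k = 5` fold
cross-validation, selecting by **mean held-out-fold AUC-PR** (the metric
most sensitive to minority-class ranking under 1:8 imbalance). Degenerate
folds (a held-out fold with one class) are skipped with `NA`; ties resolve
to the first-sampled configuration, which keeps selection deterministic
under the seed.

## Metrics: numerical conventions

`compute_panel()` evaluates eight metrics at threshold 0.5:

- **MCC** with the conventional 0/0 → 0 when any margin of the confusion
  table is empty.
- **F1** defined as 0 when precision + recall = 0.
- **AUC-ROC** via the Mann–Whitney rank statistic (ties counted ½).
- **AUC-PR** as non-interpolated **average precision**:
  $\sum_t (R_t - R_{t-1}) P_t$ over distinct-score thresholds. This is the
  step-wise estimator; it differs from trapezoidal PR interpolation, which
  is known to be optimistic.
- `summarize_across_tissues()` reports per-metric cross-tissue means/SDs
  and an **average rank** per model family using fractional ranks on
  descending MCC.

`compute_panel()` refuses single-class truth vectors and scores outside
[0, 1] rather than returning misleading numbers.

## Synthetic cohorts: what they emulate — and what they do not

`generate_cohort(synthetic_config(...))` emulates the *shape* of a curated
multi-tissue ACP dataset:

- unequal per-tissue counts (defaults from Breast 180 down to Brain 40);
- log-normal lengths (median 17, `sdlog` 0.35) clipped to [10, 100],
  matching the short-peptide regime of ACP databases;
- `"uniform"` or `"natural"` (UniProt-like frequency) residue backgrounds;
- a `duplicate_rate` (default 0.1) that re-emits sequences under a second
  tissue, reproducing the cross-tissue duplication that makes group-aware
  splitting necessary;
- **planted per-tissue dipeptide signals**: generation walks the sequence
  emitting, at each step, either the tissue's whole target dipeptide with
  probability $q = \min(0.9,\; 0.02\,( \text{multiplier} - 1))$ or one
  background residue. Multiplier 1 gives $q = 0$ — the exact null, where
  tissue labels are exchangeable. The base insertion rate 0.02 per step was
  fixed once, from the detectability requirement that multiplier 10 puts
  roughly one extra motif per median-length peptide (17 × 0.18 ≈ 3 motif
  emissions against an expected background rate of ≈ 0.04 per dipeptide
  slot), and was not adjusted afterwards.

What passing the synthetic benchmarks **does** show: the pipeline is wired
correctly end to end — encodings expose the signal a learner needs,
splitting does not leak, models beat chance exactly when signal exists, and
importance extraction points back at the planted feature.

What it does **not** show: performance on real curated data. Real tissue
signals are not single dipeptides; they are diffuse, weaker, confounded
with database composition, and correlated across tissues. Synthetic MCCs
around 0.8 at multiplier 10 say nothing about attainable MCC on real
cohorts.

## Problem sizes and runtime

Typical validation sizes used throughout the tests and the acceptance
script: 9 tissues × 200 entries = 1 800 entries, 473 features. One full
nine-task xgboost benchmark (generate, encode, split, train, evaluate)
takes ≈ 8 s single-threaded; the full acceptance script ≈ 15 s; the test
suite (≈ 6 700 assertions) ≈ 1 min.

## Known limitations

- The `solver` hyperparameter axis is an annotation, not a behaviour.
- `mtry` is fixed at 21 rather than tuned.
- KNN probability estimates are neighbour-vote fractions, not calibrated.
- The keyword dictionary is small and precision-oriented; recall on messy
  real annotations would need expansion.
- The minimum-IC50 conflict rule is optimistic by construction;
  alternatives (median, most-recent source) are not implemented.
- Per-entry one-versus-rest labelling means multi-tissue peptides are
  positives in several tasks; a multi-label formulation is out of scope.
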