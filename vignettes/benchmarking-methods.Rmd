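---
title: "Benchmarking methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

classbench is a benchmarking engine: it does not contribute a new learning
algorithm, it contributes a *procedure* — a disciplined way of comparing
classification and feature-selection algorithms on tabular data so that the
numbers coming out are attributable to the algorithms rather than to
resampling mistakes. This vignette records the procedure, its assumptions,
and the choices we made where more than one defensible convention exists.

## The resampling model

A benchmark is described by a `benchmark_plan()`: a splitting scheme
(stratified Monte Carlo or stratified k-fold), an outer count, an inner
(nested) count, a training fraction, a feature-count grid, a selection
metric, and one integer seed.

**Monte Carlo** draws, per class and per iteration, a random
`round(train_fraction * n_class)` training subset (clamped so both sides
keep at least one sample of every class). Class proportions are therefore
preserved to rounding. The default `train_fraction` is 2/3; it is an exposed
parameter, not a claim about the one true fraction. **k-fold** deals each
class's shuffled members round-robin into folds, continuing the deal counter
across classes, which yields validation sets that partition the samples,
differ in size by at most one, and are stratified. Stratification is a
deliberate choice: without it, small classes can vanish from a training
side, and one-vs-rest metrics on the validation side become undefined far
more often.

**Nested selection.** With `nested >= 1`, each outer training set is
re-split by the same scheme. Every candidate option — a hyperparameter
combination, or a feature-subset size — is scored on every inner validation
set with the selection metric (default AUROC, chosen because it applies to
probabilistic predictions and is insensitive to class imbalance). The chosen
option maximizes the *mean* across inner folds (mean rather than median: with
the default 3 inner folds a median is just the middle order statistic and
discards two of three measurements). Ties go to the earlier combination in
registry order — so defaults win ties against alternatives — and to the
*smaller* feature count (parsimony). The chosen option is retrained on the
full outer training set and evaluated once on the outer validation set.

**Determinism.** Every cell (outer iteration x algorithm, plus inner
coordinates) derives its own seed from the plan seed and the cell's indices
through a multiplicative mixing function, so the entire benchmark is a pure
function of `(dataset, plan, seed)` and output files are byte-reproducible.
Because the outer-cell training seed does not depend on what happened inside
the nested folds, a nested run whose search space contains exactly one
option reproduces the corresponding basic run bit for bit — a property the
test suite asserts on both schemes.

**Failure containment.** A cell whose adapter errors (a learner that cannot
handle a degenerate partition, say) is recorded in the run log with its
message and elapsed time, and the benchmark continues; only invalid
configuration aborts a run. Real multi-algorithm benchmarks routinely
contain a few failing combinations, and losing the whole run to one of them
would bias comparisons toward robust-but-weak learners.

## Preprocessing and leakage

Preprocessing parameters are fitted on each training partition only — outer
or inner — and applied unchanged to the corresponding validation partition.
The engine's purpose is unbiased comparison, and fitting scalers or imputers
on pooled data is precisely the kind of leakage it exists to prevent; the
test suite asserts that training rows transform identically whether or not
validation rows are present.

Order of operations: **impute → one-hot encode → robust scale**.

* *Imputation*: median for numeric features, mode for categorical features
  (ties broken by first-appearance order). A feature entirely missing in a
  training partition is an error rather than a guess.
* *One-hot encoding*: one indicator per training-observed level, columns
  named `feature=level` in first-appearance order. A level seen only at
  apply time yields all-zero indicators — the model cannot be asked about a
  level it never saw.
* *Robust scaling*: `(x − median) / IQR` with linear-interpolation
  (type-7) quantiles. The quantile convention matters: IQR values differ
  across conventions, so it is fixed and documented. A constant feature
  (IQR 0) is centered with divisor 1 instead of dropped, keeping the feature
  count stable across folds — important because feature-count grids are
  expressed in post-encoding columns.

Feature-subset sizes refer to post-encoding columns, and the grid (default
1, 3, 5, 10, 15, 20, 50, 200) is clipped to the available feature count per
inner fold.

## Metrics

All 15 metrics are computed one-versus-rest. For binary problems the
positive class is the *lexicographically second* class level unless
overridden — an arbitrary but fixed convention, documented because PPV, F1
and the rate metrics are asymmetric. For more than two classes, each metric
is computed once per class against the rest (using that class's probability
column for AUROC and Brier) and averaged with equal class weights: macro
averaging, so minority-class performance is not drowned out.

AUROC uses the Mann–Whitney midrank form — the proportion of
(positive, negative) pairs where the positive scores higher, ties worth 1/2
— and the tests check it against an independent brute-force pairwise oracle
to 1e-12. A confusion-table ratio with a zero denominator yields 0 and the
metric id is flagged in a `"degenerate"` attribute; this keeps the tidy
output rectangular without silently propagating NaN. AUROC on a single-class
validation truth is the one exception: it is recorded as missing (`NA`),
since 0 would be a meaningful-looking lie. The Matthews correlation
coefficient is clamped to [-1, 1] against floating-point overshoot.

Probability vectors from adapters are clamped to [0, 1] and renormalized;
rows summing to zero become uniform. Discrete predictions are the argmax
with ties broken toward the earlier class level. Adapters that only emit
labels are wrapped into degenerate one-hot vectors, so downstream code sees
a single prediction contract.

## The algorithm registry

Classifiers and rankers from established R packages sit behind one adapter
contract (`fit(x, y, params)` / `predict(model, x)` on a numeric matrix and
a sorted-level factor). Hyperparameter grids are declarative YAML files, one
per algorithm, shipped under `inst/algorithms/`; each file names the default
combination and the alternative grid, and the Cartesian product of the grid
(minus any cell equal to the default) forms the alternatives. The grids are
curated, functional search spaces — small enough to run at desk scale,
varied enough that nested selection has real choices — not an attempt to
enumerate each package's full parameter space. `register_classifier()` and
`register_ranker()` are exported so new algorithms plug in at run time under
the same contract and conformance expectations.

Multiclass handling is delegated to each underlying learner's own strategy.
Two adapter-level accommodations are worth noting: glmnet requires at least
two columns, so single-feature matrices are padded with a constant zero
column (coefficient 0, harmless); and formula-based learners see positional
safe names internally because post-encoding feature names contain `=`.

## Rank aggregation

Per-fold feature rankings are aggregated by Borda count with the `F − r`
scoring variant (first of `F` earns `F − 1` points, last earns 0). Summed
points are, up to an affine transform, the negative rank sum, so ordering by
descending total is provably identical to ordering by ascending mean rank
when all lists are full permutations — the tests assert this identity on
random instances, and the feature-ranks output file reports both the totals
and the mean raw rank. Ties break alphabetically by feature name.

## File formats and conventions

Delimited files carry a header row and a leading sample-identifier column;
the class column is named `Class` (case-insensitive) by default and is
overridable, since no universal convention exists. Transposed dialects
(`.ttsv`, `.tcsv`) are re-oriented on read. ARFF files are parsed and
written through the foreign package; because ARFF has no row names, the
package writes a leading `sample_id` string attribute and consumes an
attribute named `sample_id`/`id` (case-insensitive) on read, synthesizing
`S1..Sn` identifiers otherwise, and uses the last attribute as the class by
ARFF convention. The tokens `?`, `NA` and the empty string all read as
missing; files are written with `NA` (delimited) or `?` (ARFF). Multiple
input files merge on the intersection of their sample identifiers, keeping
the first file's order, with feature-name collisions and label disagreements
rejected rather than silently resolved.

One honest limitation of delimited text: a column with no observed values
cannot carry its numeric/categorical kind through a round trip (ARFF can,
via its attribute declarations). Kind inference treats a column as numeric
only if every non-missing cell parses as a number.

## The synthetic generators

`generate_null()` emulates the no-signal control condition: 500 samples, 20
standard-normal numeric features, 10 categorical features, binary labels
drawn independently of everything. Categorical level count (3) and class
balance (0.5) are unstated in the original condition and fixed here at
those conventional values. This dataset is the package's core verification
instrument: any systematic departure of AUROC from 0.5 on it would expose
leakage somewhere in the pipeline. `generate_signal()` plants a mean shift
of `effect_size` standard deviations in a known subset of numeric features
and returns the ground-truth names alongside (the CLI writes them as a
`.truth.txt` sidecar), enabling recovery tests for rankers and the
feature-count search.

What the generators do *not* emulate: correlated features, heavy-tailed or
mixed distributions, label noise, missingness mechanisms that depend on the
data, and class imbalance beyond a Bernoulli parameter. Passing the null and
recovery suites therefore demonstrates resampling hygiene and mechanical
correctness — not that any algorithm will perform well on a particular real
dataset.

## Problem sizes used in the checks

The verification suites run at the sizes the conditions prescribe where that
is cheap (the 500-sample null condition, all three modes, 5 Monte Carlo
iterations; 20 seeded signal-recovery runs across all ten rankers; 1,000
random instances for the metric and Borda oracles; 200 random datasets for
I/O round-trips). Module-level tests use smaller datasets (tens of samples)
chosen so that each property is exercised, not so that each learner shines.
The three classifiers used in the chance-level checks (LDA, decision tree,
regularized logistic regression) were picked for speed and for spanning
linear, tree and regularized-linear families.

## Known limitations

* Joint hyperparameter-by-feature-count search is not implemented; feature
  selection runs at each classifier's supplied (default) hyperparameters.
  The search spaces multiply, and the combination is computationally
  disproportionate at desk scale.
* Datasets must fit in memory; there is no streaming or database input.
* No probability calibration or ROC-curve plotting; the outputs are tidy
  tables intended for downstream analysis tools.
* The adapter registry wraps one ML ecosystem (R's). The registration hook
  is the extension point for anything else.
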