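---
title: "Apriori feature selection and suspect-class reassignment for CTG tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apriori feature selection and suspect-class reassignment for CTG tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgfusion)
```

## The task and its structure

A cardiotocography (CTG) recording is summarised by 22 numeric features —
fetal heart rate (FHR) baseline, accelerations, decelerations, short- and
long-term variability, and FHR histogram statistics — plus an expert NSP
label: normal (1), suspect (2), pathologic (3). The public reference
dataset has 2,126 records in a roughly 78/14/8 percent imbalance. Two
properties drive the design of this package:

* several features are degenerate (DS and DR are identically zero in the
  reference export) or nearly uninformative, and
* the suspect class is not a third cluster: clinically it is a
  "not clearly normal, not clearly pathologic" call, and empirically its
  records overlap both extremes, which caps whole-dataset accuracy.

`ctgfusion` therefore (i) screens and selects features, (ii) benchmarks
classifiers on the three *pairwise* tasks to expose the overlap, and
(iii) resolves the suspect class by an ensemble vote of models trained
only on the two unambiguous classes, fusing the problem to two classes.

## Screening

`rank_screen()` runs a Kruskal–Wallis test of each feature against the
three-class label. The removal rule is `p >= alpha_remove` with
`alpha_remove = 0.999`: it is meant to catch only the degenerate
"p = 1" case, which includes every constant column, rather than to act
as a significance filter — no multiple-testing correction is applied
because nothing inferential is claimed. A chi-squared test on binned
counts behaves identically on constant columns; the rank test was chosen
because it needs no binning choice.

`mutual_information()` is the plug-in estimator on equal-frequency bins
(default 10 bins, natural log). The estimator is biased upward by roughly
(number of non-empty cells − rows − cols + 1) / 2n nats, about 0.004 at
n = 2,126 with 10 bins and 3 classes, which is why the default threshold
of 0.01 cleanly separates "weakly informative" from "noise" at the
reference sample size but should be raised for much smaller tables. Both
the bin count and the log base are arguments, not constants, because
published MI tables for this dataset do not state their estimator; exact
reproduction of third-party MI values is not promised.

## Apriori feature selection

`encode_transactions()` discretizes each retained attribute by
equal-frequency binning (default 4 bins). Quantile ties collapse bins, so
a zero-inflated count feature like "severe decelerations" may end up with
2 bins, one of which covers most records — these high-support items are
exactly what gives the miner something to find, and they are why the
binning is equal-frequency rather than equal-width (equal-width bins on
skewed features put nearly everything in one bin for every attribute,
making all attributes look associated).

`apriori()` is a classical level-wise miner: frequent single items, then
candidate k-itemsets joined from frequent (k−1)-itemsets sharing a
(k−2)-prefix, pruned by downward closure, then counted against the
transaction matrix. Two properties are enforced by construction and
checked structurally in the tests: every reported support meets the
threshold, and every subset of a reported itemset is reported. The miner
is validated against brute-force power-set enumeration on hundreds of
random instances.

One numerical edge matters in practice: if `minsupport * n <= 1`, a
single transaction qualifies as "frequent support", so *every* subset of
that transaction is frequent and the result size explodes combinatorially
(2^items). This is a property of the support definition, not of the
implementation; on class slices of fewer than ~40 records the threshold
should be kept at or above 2/n. The package leaves the threshold free and
documents the cliff here.

`class_frequent_attributes()` returns the attributes participating in
frequent itemsets of size ≥ 2. Size 1 would be vacuous under
equal-frequency binning — every attribute has a frequent single item at
any threshold ≤ 1/bins — so co-occurrence, not marginal frequency, is the
selection signal; a `min_size = 1` variant exists for comparison.
`fuse_attribute_sets()` takes the union across the three per-class sets
(commutative, associative, idempotent). On the reference analysis's
printed per-class attribute rows this union has exactly 13 attributes;
that worked example is frozen into the acceptance tests. The published
*named* list for the same selection conflicts with its own index rows
(it names attributes whose indices were removed, and includes the label
column); the package computes the union from indices and treats the name
list as unreliable, flagging the discrepancy rather than reproducing it.

`support_sweep()` reports per-class attribute counts along a minsupport
grid (non-increasing, by anti-monotonicity of support) and selects the
largest grid value at which the pathologic attribute set contains the
union of the other two — the rationale being that pathologic records are
the clinically critical class, so the shared threshold is pushed as high
as possible without losing any attribute the other classes flag. If no
grid value satisfies containment the sweep says so explicitly instead of
guessing; the fixed default `minsupport = 0.1` is then still available.

## The classifier bench

Five families, chosen to span distance-based, generative, linear,
and boosted decision rules:

| family | defaults | notes |
|---|---|---|
| `knn` | k = 5, Euclidean on min-max scaled features | k is a free choice; scaling is fitted on the training split only |
| `gaussian_nb` | variance smoothing 1e-9 × max feature variance | per-class independent Gaussians |
| `sgd_logistic` | eta0 = 0.5, inverse-scaling rate t^-0.25, ≤ 10,000 updates, loss tol 1e-3 | one-sample gradient steps on the logistic loss |
| `adaboost` | 100 rounds, learning rate 0.5, depth-1 stumps, seed 25 | real-valued (SAMME.R-style) reweighting |
| `ada_rf` | 25 rounds × 50-tree forests (test profile); 500 × 1,000 (paper profile) | discrete SAMME over random-forest base learners |

The Ada-RF "paper" profile reproduces the reference architecture at full
scale; the default "test" profile keeps the same two-level structure
(boosted forests, weighted resampling, learning rate 0.5) at desk scale.
The profiles differ only in rounds × trees; switching is one argument.
Scores for ROC/AUC are class probabilities where the model has them and
the logistic of the boosting margin otherwise — a monotone choice that
leaves AUC invariant to the particular squashing.

Determinism is a contract: every stochastic component (splits, SGD
shuffling, KNN tie-breaks, forest growing) is seeded explicitly, and the
test suite asserts bit-identical refits. One subtlety: `ranger`'s
weighted bootstrap consumes R's global RNG in addition to its own `seed`
argument, so the boosting loop pins both; without this, Ada-RF results
depend on ambient RNG state.

`benchmark_models()` ("Model 1") evaluates every (classifier, class pair,
feature set) cell on one stratified 0.75/0.25 split. A single split —
rather than cross-validation — matches the reference protocol; the split
seed is an argument, and cells on external data will not reproduce any
published table exactly because that table's split seed is unknown.

## Suspect reassignment

`predict_suspects()` ("Model 2") trains KNN, Gaussian NB, SGD logistic
and AdaBoost on *all* normal and pathologic records — suspects never
contribute labels, so holding data out here would only waste training
signal; the evaluation split applies downstream. Each suspect record
receives four votes in {1, 3}; `integrate_votes()` takes the majority
and lets AdaBoost arbitrate 2–2 ties, AdaBoost being the strongest of
the four single models on the pairwise bench. Two alternative policies
(accuracy-weighted votes; unanimity-or-abstain) are available behind the
`policy` argument for sensitivity analysis.

`relabel_suspects()` rewrites only the suspect labels and keeps a
provenance table; `evaluate_fusion()` then compares the relabeled
dataset against the two blanket baselines (all suspects → normal, all
suspects → pathologic) under the same classifier and split.

On real data the reassignment has no ground truth — that is the point of
the synthetic generator. Agreement rates between single models and the
fused vote are computable everywhere; *accuracy* of the reassignment is
only measurable against the generator's latent labels.

## The synthetic generator: what it emulates, what it does not

`synthetic_ctg_spec()` defaults encode the study conditions: 2,126
records in the 1655/295/176 imbalance, 22 attributes with CTG-plausible
locations and scales, constant DS/DR, zero-inflated count features
(counts are rounded and truncated at zero), a set of informative
attributes mirroring the fused selection on the real data, and suspect
records drawn as a 0.7/0.3 mixture of the normal and pathologic
generating distributions with the latent side recorded. Class
separation on informative attributes is several standard deviations by
default — a regime where reassignment accuracy is identifiable — and a
`separation` multiplier scales it down for harder regimes.

Deliberately not emulated: within-class feature correlation (features
are conditionally independent given the class, matching the Gaussian-NB
assumption and making its behaviour analytically predictable in tests),
the real marginal shapes beyond zero-inflation, and any FHR time-series
structure (the method operates on extracted features only). Passing
tests on synthetic data therefore demonstrate the machinery —
selection, mining, voting, bookkeeping, determinism — not clinical
performance; real-data cell values additionally depend on an unknown
split seed and binning scheme and are expected only to land in the same
regime, with the same orderings (pair 1–3 easiest; fused relabeling
beating both blanket baselines).

## Numerical choices and degenerate inputs

* Equal-frequency binning uses type-7 quantiles with `include.lowest`;
  a constant vector yields one bin (and MI 0, and rank-screen p = 1).
* Gaussian NB floors every class variance at 1e-9 × the largest feature
  variance, so constant-within-class features cannot produce infinite
  likelihoods.
* Boosting clips stump probabilities to [1e-10, 1 − 1e-10] before the
  half-log-odds transform; Ada-RF stops early on a perfect weighted fit
  (that learner then decides alone) or when a base learner is no better
  than chance under the current weights.
* Undefined metrics (zero denominators) are `NA` plus an explicit flag,
  never silent zeros — zeros would corrupt averages across cells.
* AUC uses midranks, so tied scores contribute one half, matching
  exhaustive pair counting exactly.
* Labels stay as the original codes 1/2/3 end to end; no internal
  re-coding, so every report is traceable to the input labels.

## Problem sizes in the checked examples

The shipped tests and the acceptance script run the generator at the
full 2,126-record default where the claim concerns the study conditions
(reassignment recovery, screening thresholds) and at a few hundred
records where the claim is structural (monotonicity, determinism, report
shapes) — structural properties are size-independent, and the smaller
tables keep the whole suite comfortably interactive. The minsupport
sweep in the tests restricts to the 11 informative attributes for the
same reason; the support-threshold cliff described above is avoided by
keeping every class slice above 2/minsupport records.

## Known limitations

* The Eq.-style "accuracy" TP/(TP+FP) reported by the CTG literature is
  precision under the standard nomenclature; both it and standard
  accuracy are always reported side by side, explicitly labelled,
  because published tables are ambiguous about which was used.
* The mapping between published per-class attribute *indices* and
  attribute *names* for this dataset is internally inconsistent; the
  package computes from indices and flags the conflict.
* No association-rule confidence/lift mining and no FP-growth; support
  is the only criterion, and the level-wise miner is adequate at this
  scale.
* No cost-sensitive handling of the suspect class and no clinical
  decision thresholds: the package classifies, it does not triage.
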