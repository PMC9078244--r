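---
title: "The CSAR anti-sickling workflow: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CSAR anti-sickling workflow: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csarpipe)
```

`csarpipe` models the anti-sickling activity of small molecules as a
binary classification problem. This vignette is the package's own account
of the science: the statistical machinery, the parameters that matter,
the design choices made where the design was genuinely open, and what the
synthetic-data tests do and do not demonstrate.

## The problem and the label

Anti-sickling activity is measured as a solubility ratio: HbS solubility
in the presence of a compound divided by the drug-free control. Ratios at
or above **1.06** define the active class; the boundary is inclusive
(`label_rule(threshold = 1.06, active_if_geq = TRUE)`), so a compound at
exactly 1.06 is active. Labeling is a pure function of the ratio and the
rule — re-applying a rule never changes a label, which the tests assert
as idempotence.

The reference dataset geometry is 32 actives versus 83 inactives (a 1:2.6
imbalance) after curation of 132 raw records down to 115 unique
structures, plus 1600 presumed-inactive decoys (50 per active).

## Curation recipe

Deduplication needs a canonical structure key. The recipe, applied by
`standardize_compounds()`, is: keep the largest fragment (dropping salts
and solvents), neutralize formal charges where a neutral form exists, and
compare OpenBabel canonical SMILES. Two caveats are deliberate:

* Canonicalization is *not* tautomer-invariant — OpenBabel has no
  tautomer canonicalizer. Distinct tautomer drawings of one compound will
  survive deduplication; this is a documented limitation of the recipe.
* Duplicates whose activity conflicts (one active, one inactive) abort
  with an error instead of being silently merged. Such pairs are exactly
  the activity cliffs the MODI gate exists to detect, and silently voting
  them away would bias the modelability estimate.

## Descriptors

The package natively computes **substructure counts**: cell *(i, j)* is
the number of distinct matches (deduplicated by atom set) of SMARTS
pattern *j* in molecule *i*. The shipped registry
(`subfp_patterns()`) is this package's own SMARTS rendering of the twenty
named functional-group patterns most relevant to anti-sickling activity
(conjugated double bond, aryl chloride, Michael acceptor, the vinylogous
carbonyl family, …) — it is a curated subset, not a re-implementation of
a full 307-bit dictionary, and pattern-level counts may differ from other
toolkits on edge cases (tautomers, charged aromatics). The other ten
fingerprint classes in `fingerprint_registry()` (CDK, E-state, MACCS,
PubChem, Klekota–Roth, 2D atom pairs, and count variants) are
external-only: their vectors are ingested from PaDEL-dialect CSVs. The
registry records the advertised MACCS width of 116 bits even though the
classes' stated 16,092-bit total implies the conventional 166 keys; the
discrepancy is flagged in the docstring rather than silently corrected.

Lipinski profiles (`compute_lipinski()`) use the OpenBabel backend's MW,
atomic-contribution logP, and donor/acceptor counts. The logP
parameterization differs slightly from other Ghose–Crippen
implementations; the chemical-space analysis this feeds is descriptive,
so small numeric deviations are tolerated by design.

## Filtering and its leak

`filter_near_constant()` keeps descriptors whose sample standard
deviation (n−1 denominator) **strictly exceeds 0.1**. The filter is fitted
on the full matrix *before* balancing and splitting, mirroring the
original pipeline order. This is a known, deliberate information-leak
tradeoff: the SD filter sees compounds that later become external-set
members. Because the filter is label-blind, the leak is mild, but it is
documented rather than silently "fixed", and the filter is applied once
rather than re-fitted inside each resampling iteration.

## Modelability: MODI

For each compound, find its first nearest neighbor by Euclidean distance
in descriptor space; MODI is the mean over classes of the fraction of
compounds whose neighbor shares their class. The normalized-distance
variant divides by the global mean off-diagonal distance — a strictly
monotone rescale, so the neighbor map, and therefore MODI itself, is
invariant to it (the tests assert this). Neighbor ties at exactly equal
distance are broken by lowest row index for determinism; on degenerate
data this tie rule may differ from other implementations. Datasets with
MODI ≤ 0.65 abort the pipeline unless `force = TRUE`. By default MODI is
computed on the full labeled set (the filtered matrix), not the balanced
subset; both are accessible through the stage functions.

## Balancing and splitting

Two undersamplers are provided and used exactly where the original
workflow used them: **random** undersampling (seeded, without
replacement) for modeling, and **Kennard–Stone** undersampling for the
applicability-domain analysis. Kennard–Stone is the classic max–min
procedure — first two picks realize the maximum pairwise distance, each
later pick maximizes its minimum distance to the selected set — with ties
broken by lowest row index, making it fully deterministic; the test suite
proves equality with an exhaustive greedy oracle on all instances up to
n = 50.

`split_internal_external()` defaults to `ratio = 0.75`. The study design
describes an "8:2" split, but its printed cardinalities — 48 internal
(24 per class) and 16 external (8 per class) from the 64-compound
balanced set — are a 3:1 split; 0.8 × 32 = 25.6 cannot round to 24. The
package follows the printed counts: per-class internal size is
`round(ratio × n_class)`, which reproduces 48/16 at the default and 8/2
on a 10-compound balanced set. Any other ratio can be passed explicitly.

Cross-validation (`make_cv_scheme()`) is stratified 5-fold with 3
reshuffled repeats; leftover compounds go to the currently smallest
folds, so 48 compounds yield fold sizes {10, 10, 10, 9, 9} with per-class
balance to ±1. Resampling (`make_resampling_plan()`) re-stratifies the
split 100 times by default, each iteration with its own derived seed.

## The classifier and its tuning

The model is a random forest (Gini-impurity trees via the `randomForest`
package). Tuning follows the two-step protocol: `n_tree` is selected over
{100, 200, …, 1000} by stratified 10-fold CV accuracy, taking the
smallest grid value within one SD of the best (the grid is stated by the
protocol; the one-SD tie rule is this package's choice, favoring smaller
forests). `m_try` is then chosen by a stepwise out-of-bag search
equivalent to the classic tuneRF procedure: start at `floor(sqrt(p))`,
step by factor 2 in both directions, stop when the relative OOB
improvement drops below 5%. The search is implemented natively so its
trace is a testable contract (the suite replays the stepping rule from
the recorded OOB errors). Whether tuning is repeated inside every
resampling iteration is configurable (`tune = "per_iteration"`, the
default, or `"once"`, or `"none"` with fixed parameters); equivalence
with the original R implementation is statistical, not bitwise, since RF
randomness differs.

Per iteration, the evaluation pools the held-out predictions of all
5 × 3 CV folds into one confusion matrix; aggregates are mean ± SD (n−1)
over iterations. MCC with a zero denominator (degenerate margin) is
defined as 0 so that degenerate folds remain aggregable. AUC is the
rank-based (midrank ties) Mann–Whitney normalization, identical to the
trapezoidal ROC area; the independent cross-check in the tests is pROC.
Decoy evaluation scores each iteration's model on the decoy block; since
every decoy is truly inactive, decoy accuracy equals decoy specificity,
and accuracy is the only decoy statistic reported.

## Importance and class statistics

`mdgi_ensemble()` fits one forest per `m_try` in
{2, 3, 5, 7, 9, 11, 13, 15, 17, 19, 20} at a fixed 100 trees and averages
each descriptor's mean decrease of the Gini index across the ensemble, so
the ranking is not hostage to one `m_try` choice. The source protocol
says "10 RF models" but enumerates these eleven values; the explicit list
is taken as authoritative (11 models, overridable). Gini importance is
used rather than permutation importance, following the robustness
argument in the random-forest literature. Ranks are deterministic: ties
in mean MDGI break lexicographically by descriptor code.

Per-feature class comparisons (`compare_classes()`) gate on a
Kolmogorov–Smirnov normality test against a normal with sample-estimated
mean and SD — the classic `ks.test` usage, which carries the Lilliefors
caveat (estimated parameters make it anticonservative); this mirrors the
quoted procedure rather than statistical best practice. Non-normal data
(the usual case for count descriptors) goes to the two-sided
Mann–Whitney U test, computed with the normal approximation and tie
correction uniformly — count data is tie-heavy, where the exact
distribution is unavailable anyway, and one documented branch beats a
data-dependent switch. The `test` argument can force either branch.
Stars follow the convention `*` p ≤ 0.05, `**` p ≤ 0.001, `***`
p ≤ 0.0001. No multiple-testing correction is applied, matching the
original analysis; this is a documented limitation, and per-feature
p-values should be read accordingly.

## Applicability domain

`fit_ad()` autoscales columns (the scaling choice is unstated in the
source protocol; autoscaling is this package's choice, appropriate for
heterogeneous count descriptors), fits PCA on training compounds only,
and declares the axis-aligned inclusive [min, max] box of the training
scores on the first `n_pc = 2` components to be the domain — the literal
bounding-box approach matching the 2-D scores-plot convention.
Predictions outside the box are still returned, only flagged. Leverage,
distance-to-centroid and density domains are out of scope.

## The synthetic generator

`generate_dataset()` emulates the study conditions so every stage is
testable without downloads: 32/83 compounds, ratios uniform in
[1.06, 1.30] (active) and [0.85, 1.059] (inactive), and 45 count-valued
descriptors — the filtered substructure-count dimensionality — of which
10 are class-informative, echoing the 10 significant substructure counts
in the reference analysis. Counts are Poisson draws (the winning
descriptor class is count-valued; a Bernoulli mode exists for binary
classes) with means λ_active = 3, λ_inactive = 1 for informative columns
and λ_noise = 1 elsewhere; these defaults were chosen once as a moderate,
realistic signal (MODI ≈ 0.9, CV MCC ≈ 0.87) and are not tuned
thereafter. The strong-separation checks explicitly override
λ_active = 8. Decoys are *descriptor-level* emulations: property-matched
rows (MW/AlogP within a fractional 0.10, donor/acceptor counts within
±1 — desk-scale stand-ins for the much looser property windows of public
decoy services) drawn from the inactive count distribution, with no
fabricated SMILES.

What passing tests on this generator show: the pipeline's plumbing,
determinism, and statistical behavior (signal recovery, null calibration)
are correct. What they do not show: performance on real chemistry — real
fingerprints are sparse, correlated and structured by scaffolds, none of
which independent Poisson columns emulate. Real-data performance claims
require real descriptor matrices.

## Numerical and degenerate-case choices

* Seeds: every stochastic stage takes an explicit seed; derived seeds are
  drawn below 2³¹. Same seed ⇒ bit-identical outputs, asserted in tests.
* Nearest-neighbor and Kennard–Stone ties: lowest row index.
* MCC 0/0 → 0; degenerate (all-tied) class comparisons are flagged and
  return p = 1 rather than erroring.
* Constant columns: dropped by the SD filter; dropped again defensively
  before PCA; a constant descriptor that reaches the forest gets MDGI 0.
* Problem sizes in the shipped checks are desk-scale by design — e.g.
  resampling plans of 3–15 iterations in tests (the full 100-iteration
  default remains available), 50-seed medians for planted-feature
  recovery, and a 10-dataset average for the no-signal cross-validation
  null, whose single-dataset value has a between-dataset SD of ≈ 0.09 at
  48 training compounds and is therefore only meaningful in expectation.

## Known limitations

* Only the substructure/substructure-count classes have a native backend;
  the other ten fingerprint classes must arrive as CSVs.
* The SMARTS registry is a 20-pattern curated subset; counts are not
  guaranteed to match any external dictionary bit-for-bit.
* The normality gate inherits the Lilliefors caveat; p-values are
  uncorrected for multiplicity.
* The applicability domain is a 2-PC bounding box: conservative along
  principal axes, permissive in the box corners.
* Raw HbS solubility measurements are out of scope — inputs arrive as
  precomputed ratios.
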