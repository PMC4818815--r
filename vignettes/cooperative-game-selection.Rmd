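---
title: "Cooperative-game feature selection: model, estimators, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative-game feature selection: model, estimators, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapleyFS)
```

## The problem and the model

Gene-expression classification works in the p ≫ n regime: thousands of
correlated features, tens of samples, often imbalanced classes. Two failure
modes of univariate filters motivate this package. First, a feature can be
individually uninformative but decisive jointly with a partner (the XOR
caricature); ranking by marginal relevance never sees it. Second, the
selected subset can be unstable: rerun the selector on a resampled cohort and
a very different gene list comes back, which undermines biological
interpretation.

`shapleyFS` treats features as players in a cooperative game and scores each
one by its Shapley value — its average marginal contribution over coalitions
of other features. Three phases:

**Phase 1 — prefilter.** Optional per-feature z-scoring (population sd;
zero-variance features map to 0), then the top k features by Fisher ratio or
mutual information. This is purely computational triage: the coalition game
is quadratic in the number of features, so the game is played on the
filtered survivors (default k = 300).

**Phase 2 — Shapley weighting.** All quantities are plug-in estimates on
discretized data (below). For features i, j and the class variable:

* ψ(i, j) = 1 iff CMI(f_j; class | f_i) > QMI(f_j; class), else 0 —
  "conditioning on i tells us more about the class through j than j's
  (utility-scaled) marginal information"; equality counts as redundancy.
* The relevance change of coalition K under i is
  mean_{j ∈ K} [CMI(f_j; class | f_i) − QMI(f_j; class)].
* Payoff Δ_i(K) = 1 iff the relevance change is ≥ 0 **and**
  Σ_{j∈K} ψ(i, j) ≥ |K|/2; else 0.
* φ_i = Σ_{|K| = k, K ∌ i} Δ_i(K) · k!(n−k−1)!/n!, coalition size k = 2 by
  default, giving φ_i ∈ [0, 1/n].

QMI is mutual information with each cell term multiplied by a utility. The
utility here is the feature's Fisher ratio, constant across value pairs, so
operationally QMI(f_j; class) = FR(f_j) · MI(f_j; class). The effect is a
per-feature rescaling of the ψ threshold: a marginally strong feature (large
FR) demands more conditional evidence before partners count as
interdependent, which damps the influence of sampling noise on the binary
index and is the mechanism behind the method's stability claim. Setting
`shapley.utility = "constant_one"` recovers the plain-MI variant as an
ablation.

**Phase 3 — forward selection.** Greedy maximization of the victory score
V(f) = (1 + ŵ(f)) · g(f), with ŵ the min–max normalization of φ and
g(f) = SU(f; class) − mean_{s ∈ S} SU(f; s), SU being symmetric uncertainty
2·MI/(H + H). Ties break toward larger φ, then the smaller original column
index, making the whole pipeline deterministic.

## Estimators and numerical conventions

* **Discretization.** Continuous features are discretized with
  equal-frequency binning, default B = 5 bins (`bins` config key). Codes are
  assigned by sorted position, bins holding ⌈n/B⌉ ± 1 samples; ties are
  ordered by value then original index, so heavily tied values may straddle
  a boundary while bin counts stay balanced. A constant feature collapses to
  a single occupied bin (entropy 0), not a uniform spread. Class labels are
  used as categorical codes directly. Equal-frequency is preferred over
  equal-width because microarray intensities are heavy-tailed; B = 5 keeps
  ≥ 2 expected counts per cell of a 5 × 2 table at n ≈ 50, the small end of
  the intended regime.
* **Information theory.** Everything is in bits, 0·log 0 := 0, computed from
  empirical contingency tables via entropy decompositions
  (e.g. CMI = H(X,Z) + H(Y,Z) − H(Z) − H(X,Y,Z)). Plug-in MI and CMI are
  mathematically non-negative; floating-point round-off below zero is
  clamped to 0 so the strict comparison in ψ cannot flip on noise. The test
  suite holds these to within 1e−12 (absolute) of an independent
  cell-by-cell brute force.
* **Scale note.** ψ compares CMI in bits against QMI in Fisher-scaled bits.
  That mixed scale is inherent to the method as defined — the utility is the
  point, not a bug — and is implemented literally.
* **Fisher ratio.** Two classes: (μ̂₁ − μ̂₂)²/(σ̂₁² + σ̂₂²) with population
  variances. The sum in the denominator (not the difference) is the standard
  definition; a difference can be non-positive and leaves the score
  undefined. With > 2 classes the score is the mean over unordered class
  pairs, which keeps the two-class case exact. Zero within-class variance
  with separated means returns the finite cap 1e12 rather than infinity so
  downstream utility products stay finite.
* **Shapley computation.** The O(n²) CMI/QMI cache and the coalition
  enumeration are C++ (Rcpp); coalition loops are pure table lookups, so the
  default n = 300, k = 2 run (~90k cached CMI values, ~13M pair lookups)
  takes about a second. k > 3 is allowed but warns: the subset count grows
  combinatorially. Exhaustive-enumeration equivalence is tested for n ≤ 10,
  k = 1..3.

## Design decisions where the method is underspecified

* **g(f) and V(f).** The victory phase names a criterion g (SU) and a weight
  w but no closed forms. We use the SU relevance-minus-mean-redundancy form
  for g (the natural SU transplant of the minimum-redundancy
  maximum-relevance rule) and V = (1 + ŵ)·g rather than ŵ·g: raw φ is
  legitimately 0 for many features, and a pure product would annihilate every
  such candidate; (1 + ŵ) degrades gracefully to pure SU ranking when all
  weights are equal. Both alternatives remain switchable
  (`select.mode = "product"` / `"su_only"`) for sensitivity checks.
* **Eq.-level strictness.** ψ uses strict >, the payoff's two conditions use
  ≥, and the ≥ |K|/2 boundary is inclusive (a size-2 coalition qualifies
  with one interdependent member). Ties CMI = QMI count as redundant.
* **Shapley sum.** φ sums coalitions of a single configured size once each
  (all two-member subsets by default), not over all sizes.
* **JC's correlation credit.** JC_i(k) = (|S_i ∩ S_o| + SC_i)/k. SC is
  described only as a sum of absolute correlations between differing
  features; summing all cross-pairs can exceed k and break the stated [0, 1]
  bound. We match each feature of S_i∖S_o to its best absolute Pearson
  correlate in S_o∖S_i (computed on the full data; zero-variance features
  correlate 0), which preserves the bound and rewards selecting a surrogate
  of a reference feature. Resampling uses the m training folds of an m-fold
  stratified partition (m = 10 default).
* **SVM parameterization.** The harness's Gaussian kernel is
  K(x, y) = exp(−‖x − y‖²/(2σ²)) with σ = 20 by default ("kernel width" is
  the only reading that makes a standard deviation of 20 meaningful). With
  no SVM provider installed in the target environment, `svm_rbf` is a
  least-squares SVM (kernel ridge on ±1 targets, one-vs-rest); KNN, Gaussian
  naive Bayes, and a greedy Gini tree are likewise compact internal
  implementations. They are an evaluation harness, not a contribution.
* **Multiclass synthetic means.** Per-feature class means are scalars, so
  mutually equidistant placement ("simplex") is impossible beyond two
  classes; means are equally spaced with adjacent separation equal to
  `effect_size`, exact in the two-class case.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` draws unit-variance Gaussian features: `n_informative`
with class-shifted means, `n_redundant_per_informative` correlated copies per
informative feature (parent plus Gaussian noise scaled to hit
`redundancy_corr`; 1.0 gives exact copies), and `n_noise` class-independent
features. The default fixture (100 samples × 2000 features, 2 balanced
classes, 10 informative, 4 copies each at r = 0.9, effect 2 sd, seed 1234) is
a desk-scale analogue of the smallest published microarray panels.
Generation is Mersenne-Twister, fully determined by `seed`, and never touches
the caller's RNG state.

Not emulated: heavy-tailed intensity distributions, batch/dye artifacts,
class imbalance, and — importantly — *interaction-only* signal: the planted
features are all marginally informative. A green recovery test therefore
establishes that the pipeline finds and de-duplicates correlated marginal
signal at realistic dimensionality; it does not establish XOR-style epistasis
discovery on noisy data. On that point the test suite is explicit: with
random finite samples, plug-in CMI bias makes ψ fire spuriously for
unrelated feature pairs, and since the payoff is binary (magnitudes are
ignored), most features saturate near the φ upper bound 1/n. The
XOR-detection property is exercised on full-factorial designs where empirical
independence is exact — the regime in which the game's discrimination is
provable — and the randomized planted-recovery tests rely on the SU forward
phase as much as on φ. This is a measured property of the method as defined,
not an implementation artifact.

## Limitations

* The coalition game is O(n²) in cached CMI values and O(n·C(n−1,k)) in
  lookups; k = 2 at n = 300 is interactive, k = 3 at n = 300 is minutes,
  beyond that is not desk-scale.
* Binary payoffs discard effect magnitude; two features barely passing the ψ
  threshold count as much as a decisive pair. The Fisher-ratio utility
  mitigates, but does not remove, estimator-bias sensitivity at small n.
* Missing values are a hard error by design: imputation would silently
  change every estimator in the chain.
* Precision/recall/F are reported for two-class problems only; multiclass
  runs report accuracy.
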