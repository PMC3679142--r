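---
title: "Predicting heterodimeric complexes from weighted PPI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting heterodimeric complexes from weighted PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdimer)
```

## The problem and the model

A weighted PPI network assigns every observed interaction a positive
reliability score (in yeast compendia, typically a product of
socioaffinity indices and log-likelihood scores — positive and strongly
right-skewed). Density-based complex finders cannot decide whether a
single edge is a complex, so `hdimer` poses heterodimer detection as
supervised binary classification of interacting pairs.

The model has three parts.

**Feature mapping.** Seven numbers per pair: the internal weight (F1),
the maximum and minimum weight from either member to a protein outside
the pair (F2, F3), the strongest common neighbour in the min-weight sense
(F4), the largest weight asymmetry across a common neighbour (F5), and
the larger/smaller total domain counts of the two proteins (F6, F7).
The working assumption is that a heterodimer shows a reliable internal
edge embedded in a weak neighbourhood, while a pair inside a bigger
complex has strong common neighbours; domain-rich proteins tend to sit in
bigger assemblies.

**Domain composition kernel.** Proteins are equivalent when their domain
multisets (identifiers *with counts*) are identical; two equal-size
protein sets are equivalent when some permutation aligns them into
pairwise-equivalent members. `kdc()` is the indicator of this set
equivalence. Since the relation is reflexive, symmetric and transitive it
partitions any example collection into classes; the Gram matrix, after
reordering, is block-diagonal with all-ones blocks, so it is positive
semidefinite and a valid kernel. This differs from pairwise "genomic"
kernels built from per-protein similarities: those allow partial and
crossed matches to contribute gradually, whereas the composition kernel
fires only on an exact multiset matching (the crossed case — first
protein of X matching the second of Y — is covered by the permutation).
`set_equivalent()` is implemented for arbitrary set size by comparing
sorted canonical composition strings, which is exactly equivalent to
permutation enumeration and lets `kdc_gram()` bucket N examples by
canonical key in O(N log N) instead of N² matchings; the test suite
checks both equivalences by brute force.

**Classifier.** A convex combination
`K = (1 − α)·⟨f(x), f(y)⟩ + α·K_dc` feeds a C-SVC with separate
penalties C+ and C− for the positive and negative class, solved by
`kernlab::ksvm` on the precomputed Gram matrix with `class.weights`
(each dual coefficient is then bounded by its class's penalty, which is
the per-class-penalty soft-margin dual). Per-class penalties matter
because the rule-built datasets are heavily imbalanced (tens of positives
against thousands of negatives on real catalogues).

## Parameters that matter

* `alpha` (default 0.6, unitless, in [0, 1]): weight of the composition
  kernel. 0 is the features-only baseline; values around 0.5–0.8 are
  where the combination typically helps. The combination is implemented
  in convex form; since only the mixing ratio α : (1−α) matters to an SVM
  up to the penalty scale, an additive reading `k + α·K_dc` (α ≥ 0) is
  equivalent up to reparameterisation and is kept available as
  `kernel_config(form = "additive")`.
* `c_plus`, `c_minus` (default 1, 1): per-class slack penalties. Raising
  `c_plus` trades precision for recall on the rare class. The default
  grid in `grid_search()` spans C+ ∈ {0.5, 1, 2, 4}, C− ∈ {0.25, 0.5, 1}.
* `n_folds = 10`, `stratified = TRUE`, `seed`: folds are drawn once from
  the seed; stratification is on by default because with few positives an
  unstratified fold easily loses the positive class entirely, making
  recall undefined.
* `f5_mode`: the "maximum of differences between neighbouring weights"
  admits several readings. The default `common_abs_diff`
  (max over common neighbours of |w_ik − w_jk|) is the simplest reading
  that is not a linear combination of F1–F3; the alternatives `range`
  (F2 − F3) and `inside_minus_min` (w_ij − F3) are linearly redundant
  under a linear kernel and are kept only for comparison.
* `unannotated` (default `"pseudo"`): a protein with no domain annotation
  gets a unique pseudo-domain derived from its own identifier. This keeps
  protein equivalence reflexive (needed for the equivalence-relation
  argument) without collapsing all unannotated proteins into one class,
  which would create a large spurious kernel block. `"empty"` makes them
  mutually equivalent instead.
* `scale = TRUE`: per-feature min–max scaling to [0, 1], fit on the
  training fold only and applied unclipped to the held-out fold, so no
  information leaks from test to train. Constant training columns map
  to 0.

## Dataset construction rules

Positives are catalogued complexes of exactly two proteins whose pair is
a network edge and is not a proper subset of any other catalogued
complex. Negatives are interacting pairs co-occurring in a complex of
size > 2, excluding any pair that is itself a catalogued dimer — that
exclusion also removes dimers nested inside bigger complexes, which are
neither clean positives nor clean negatives. Two identically-membered
complexes under different names do not disqualify each other (equal sets
are not proper subsets); such a pair enters once, with merged provenance.
Pairs occurring in several large complexes are deduplicated. Examples are
ordered lexicographically so fold draws are reproducible.

## What the synthetic generator emulates — and what it does not

`generate_benchmark()` plants, per `synthetic_config()`:

* heterodimers: one strong internal edge (log-normal, meanlog 3) plus a
  few weak background attachments (meanlog 0.5) — high F1, low F2/F4;
* large complexes (sizes 3–6, internal edge probability 0.9, strong
  weights): their member pairs are hard negatives with high F2/F4,
  mirroring the rationale that within-complex pairs are harder than
  random non-edges;
* background proteins and sparse weak background edges;
* domain multisets of 1–4 identifiers per protein from a vocabulary of
  60; a fraction (default 0.3) of heterodimer pairs is grouped into
  shared exact-composition classes of about six pairs, and a
  sub-fraction (default 0.15 of all heterodimers, drawn from those
  classes) is made *hard* by wiring both members strongly to a common
  decoy neighbour. Hard pairs are indistinguishable from negatives in
  the weight features; only the composition kernel, leaning on their
  class mates' dual weights, can recover them. Classes of ~6 were chosen
  so that a held-out hard pair still sees several same-class training
  examples; with smaller classes the indicator bump is too small to
  outweigh the feature deficit.

Log-normal weights are the simplest faithful stand-in for scores built as
products of log-odds terms: positive and right-skewed. The generator does
*not* attempt to match the real compendium's weight distribution, degree
distribution, annotation coverage, or the overlap structure of real
complexes (shared subunits across complexes, which the disjoint protein
pools here avoid by construction). Passing tests therefore demonstrate
that the pipeline recovers the planted structure under the model's own
assumptions — not field performance on curated yeast data, which depends
on external files and their idiosyncrasies.

Default sizes (40 heterodimers, 20 large complexes, 300 background
proteins, ~190 labelled examples) keep a full cross-validation under a
second and the whole suite in well under a minute while leaving every
fold several positives.

Two sanity properties pin the generator to the method: the rule-based
dataset builder recovers the generator's intended labels exactly, and
flattening the generator (identical weight distributions, no composition
sharing, decoys on every heterodimer) collapses cross-validated F toward
zero — evidence that performance comes from the modelled signal, not from
leakage.

## Numerical choices and degenerate inputs

* Duplicate edge rows collapse to the **maximum** weight: weights are
  reliabilities, the more confident record wins, and the rule is
  order-independent. Self-interaction rows are dropped and counted.
  Rows with a non-numeric weight (headers) are skipped and counted.
* Empty neighbourhoods: F2–F5 default to 0, the "no competing
  interaction" limit.
* Unscaled decision ties: a decision value of exactly 0 predicts +1.
* Degenerate precision/recall (zero denominator) is reported as 0 with a
  message, never NA, so fold averages stay defined.
* PSD is asserted up to −1e−8 (relative to matrix scale for combined
  Grams): the indicator Gram is exactly PSD in theory, and double
  arithmetic keeps eigenvalues within ~1e−15 of it in practice.
* `kernlab`'s internal ±1 coding of factor levels is not part of its
  documented interface, so after fitting, the wrapper orients the stored
  decision function against the solver's own predicted labels and keeps
  the oriented coefficients; a disagreement beyond ties would warn.
* Fold averaging is the arithmetic mean of per-fold precision, recall
  and F (the mean of per-fold F, not the F of pooled counts).

## Known limitations

* The composition kernel is all-or-nothing: a single differing domain
  copy breaks equivalence. Softer domain similarity (sequence-based
  kernels) is out of scope.
* Primal feature weights — and hence `feature_contributions()` — exist
  only at α = 0; the indicator part has no feature-space coordinates.
  The ranking statistic |w_k·x̄_k| (weight times mean scaled value) is
  one reasonable reading of "contribution"; ranking by |w_k| alone on
  normalized features is another and can disagree.
* With α = 1 the classifier sees only composition classes; on data where
  classes rarely repeat it degenerates to predicting the majority class.
* Proteins are opaque case-sensitive strings; no identifier mapping is
  attempted, so network, catalogue and annotation files must share a
  namespace.
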