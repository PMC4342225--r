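---
title: "Wrapper feature selection with a genetic algorithm: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper feature selection with a genetic algorithm: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Biomedical classification tasks — translation-initiation sites, transcription
factor interactions, microarray diagnosis — routinely describe each sample by
hundreds to tens of thousands of features of which only a handful matter.
wrapfs implements *wrapper* feature selection: candidate feature subsets are
scored by the cross-validated performance of an actual classifier trained on
them, in contrast to *filters*, which score features by data statistics
alone. Wrappers can capture feature interactions that no univariate statistic
sees (the XOR fixture in this package is the canonical example), at the price
of a much larger search problem and a real risk of overfitting the selection
to the data it sees.

## The search model

A candidate subset is encoded as a binary chromosome $\theta \in \{0,1\}^n$
over the $n$ candidate features; bit $j$ marks inclusion of feature $j$. A
single-population genetic algorithm evolves a population of $r$ chromosomes
under the fitness

$$\mathrm{fitness}(\theta) \;=\; \mathrm{Performance}(\theta)\;-\;\alpha\,\frac{\sum_j \theta_j}{n},$$

where Performance is the inner-cross-validated metric of the wrapped
classifier on the masked features and $\alpha$ (default 0.15) prices the
selected-feature fraction: of two equally performing masks the smaller is
fitter, and a feature is worth keeping only if it buys more than $\alpha/n$
of performance. In hybrid (filter-then-wrapper) mode the chromosome ranges
over the filter-retained candidates and $n$ is the size of that reduced
search space, keeping the per-feature price scale-invariant.

Generations are produced by:

* **initialization** — member 1 is the all-ones chromosome (the
  all-features solution is always examined); the rest are i.i.d.
  Bernoulli(0.5) bits; all-zero chromosomes are repaired by setting one
  random bit, since an empty mask makes Performance undefined;
* **parent selection** — by default the two fittest chromosomes of the
  current population parent every offspring pair (`selection = "best_pair"`);
  a classical independent binary tournament per parent is available
  (`selection = "tournament"`). See *Design choices* below;
* **two-point crossover** (rate 0.8 per pair) — two cut positions $a < b$
  are drawn uniformly and the segment $(a, b]$ is exchanged;
* **bit-flip mutation** (rate 0.01 per bit), with the same all-zero repair;
* **generational replacement with single-member elitism** — the best member
  survives unchanged, which makes the best fitness monotone and the
  stopping rule well-defined;
* **stopping** — after `max_generations` (default 100) generations, or as
  soon as the best fitness has not changed for `stagnation_patience`
  (default 50) consecutive generations (steady state).

Fitness evaluation is a pure function of the chromosome: the inner-fold
assignment is derived once from the master seed, and no evaluation consumes
random numbers. A worker pool (`worker_count`) therefore cannot change any
result — scheduling only changes wall-clock time — which is asserted by a
determinism test.

## The wrapped classifiers

Two in-house classifiers sit behind one performance contract:

* **Gaussian naive Bayes** — empirical class priors; one Gaussian per class
  and feature; per-class variances are floored at
  $10^{-9}(\mathrm{var}_{\text{global}} + 1)$ so constant features degrade
  gracefully to the prior. Posterior ties go to the lexicographically first
  class symbol.
* **k-nearest neighbours** — Euclidean distance over the masked features,
  standardized by training mean and standard deviation (zero-variance
  features are left unscaled); `k = 5` by default. Distance ties resolve to
  the lower training index, vote ties to the lexicographically first class.

`classifier = "both"` averages the two metric values with equal weight —
the minimal unbiased aggregate, chosen because no combination rule is
canonical; selecting with two classifiers reduces the bias of the chosen
subset toward either model.

Metrics are computed from confusion counts: sensitivity, specificity, PPV,
GMean $= \sqrt{\text{sens}\times\text{spec}}$, F1, accuracy and Matthews
correlation. Any $0/0$ form evaluates to 0 — the conservative convention —
and multiclass tasks are macro-averaged one-vs-rest. The positive class of
a binary task defaults to the lexicographically last label.

## Filters and the hybrid pipeline

When $n$ is large the wrapper alone is prohibitive, so a greedy
information-theoretic filter can shrink the candidate set first (default
retention: the top 10%). All criteria are built on plug-in mutual
information over empirical contingency tables (bits); continuous features
are first discretized into 10 equal-frequency bins by ranks, which gives
exactly balanced bins for distinct values and keeps ties in a single bin.
With $S$ the already-selected set, candidate $X_k$ scores

* mRMR: $I(X_k;Y) - \frac{1}{|S|}\sum_{j\in S} I(X_k;X_j)$
* JMI: $\sum_{j\in S} I(X_k,X_j;Y)$
* CMIM: $\min_{j\in S} I(X_k;Y\mid X_j)$
* ICAP: $I(X_k;Y) - \sum_{j\in S}\max\!\big(0,\, I(X_k;X_j) - I(X_k;X_j\mid Y)\big)$

with the first pick always maximizing $I(X_k;Y)$ and ties broken by the
lowest index. A class-correlation baseline (absolute point-biserial
correlation; maximum over one-vs-rest encodings for multiclass;
zero-variance features score 0) is included for comparison studies.

## Assessment

`nested_cv()` estimates the generalization of the *whole* select-then-
classify procedure: feature selection sees only the outer-training portion
of each of the `k_outer = 5` stratified folds (wrapper methods run their own
`k_inner = 5` cross-validation inside it); the classifier is then refit on
the full outer-training set with the selected mask and scored on the
untouched outer fold. A leakage audit test traces sample indices to verify
the outer-test rows are never visible to selection. Selection robustness is
summarized by the chance-corrected stability of the per-fold subsets,

$$S(\theta_i, \theta_j) = \frac{c - k_i k_j / n}{\min(k_i, k_j) - \max(0,\, k_i + k_j - n)},$$

with subset sizes $k_i, k_j$ and overlap $c$: range $(-1, 1]$, expectation 0
for uniformly random selection (verified by simulation), averaged over all
unordered fold pairs. Comparison studies aggregate results with ranking
points (1 for the best method per dataset/metric cell, ties share the mean
rank, smallest sum wins), reduction percentages
($100\,|\text{selected}|/n$) and the performance-per-feature ratio.

## Synthetic data: what the generators emulate

No external benchmark is downloaded; three generators provide ground truth:

* `make_informative_dataset()` emulates Madelon-style hypercube-cluster
  benchmarks: two Gaussian classes whose centres are `class_sep`
  within-class standard deviations apart along a random-sign,
  equal-magnitude direction of the informative subspace, optional redundant
  features (noisy linear combinations of informative ones), label-independent
  Gaussian noise features, and optional label flipping. The equal-magnitude
  direction is deliberate: a random unit vector would leave near-zero-loading
  coordinates effectively uninformative, contradicting their ground-truth
  label. Defaults (500 samples, 10 informative + 90 noise, `class_sep = 2`,
  i.e. Bayes error about 16%) are the recovery-experiment scale; the largest
  benchmark the package means to emulate is ~2600 samples by ~500 features.
* `make_xor_dataset()` — two features individually independent of the label
  whose product sign determines it; the case where univariate ranking must
  fail and multivariate selection can win.
* `make_binary_dataset()` — 0/1 features with closed-form information
  content ($1 - H_2(p_{\text{flip}})$ bits), for exact-MI oracle tests.

A green test on these fixtures establishes that the machinery does what its
contracts say on data with known structure; it does not establish
performance on real assays, whose feature correlations, batch effects and
class imbalances the generators do not model.

## Design choices made where the design was open

* **Parent selection.** The package defaults to deterministic best-pair
  parentage and also ships a textbook independent binary tournament. The
  phrase "binary tournament selection, where the best two chromosomes in the
  population are selected to serve as parents" admits both readings; we take
  the literal one as default. Empirically the two find selections of the
  same quality on the recovery fixtures, but best-pair converges with far
  fewer distinct fitness evaluations (the population collapses onto the
  elite lineage, and the evaluation cache absorbs the clones), so it is
  several times faster per run at equal results.
* **Crossover rate semantics** — the per-pair probability of performing the
  exchange, the convention of classical GA libraries, not a per-gene
  quantity; with probability $1 - 0.8$ the children are parent copies.
* **Automatic train/test splits are stratified**; whether the original
  service stratified is unknown, but unstratified splits can produce
  class-empty sides on imbalanced data, which the contract forbids.
* **Reported per-fold metrics come from a refit** on the full outer-training
  set with the selected mask, while the wrapper's internal Performance is
  the mean inner-CV metric; the refit uses every training sample the fold
  legitimately owns without touching the outer test.
* **Header detection** in the tab-delimited reader: a first row whose
  non-last fields fail numeric parsing is a header; otherwise names
  `f1..fn` are generated. Missing values are rejected outright.

## Numerical choices

* MI/CMI are plug-in estimates in bits; CMI is computed stratum-by-stratum
  (it equals the chain-rule form exactly for plug-in estimates, which a
  property test asserts to $10^{-12}$).
* Equal-frequency codes are `floor((rank - 1) * bins / n)` with
  minimum-rank ties; integer-coded inputs with at most `bins` distinct
  values pass through with their grouping unchanged.
* The NBC variance floor, the $0/0 \to 0$ metric convention, and the
  deterministic tie-breaks (lexicographic classes, lower indices) are all
  chosen so that every code path is defined and reproducible on degenerate
  inputs.
* Fitness caching is keyed by the exact bit string and is
  semantics-preserving; identical chromosomes are evaluated once.

## Known limitations

* **The size penalty is weak relative to inner-CV noise at moderate sample
  sizes.** Dropping one feature changes fitness by $\alpha/n$ (0.0015 at
  the defaults with 100 features), while re-evaluating a slightly different
  mask on 5 inner folds of a few hundred samples moves the metric estimate
  by several times that. Masks that retain a handful of "lucky" noise
  features are therefore local optima of the fitness, and the wrapper
  typically keeps more features than the ground truth — the classic
  wrapper-overfitting phenomenon. The informative features themselves are
  recovered reliably; the selected set is just not minimal. Users who need
  aggressive reduction should raise `alpha`, supply more data, or filter
  first.
* The plug-in MI estimator is biased upward on small samples; oracle tests
  pin its exactness on the contingency table, not its bias.
* The GA is a heuristic: it reports the best solution examined, with no
  global-optimality guarantee; the steady-state stop bounds effort, not
  quality.
* Multiclass metrics are macro-averaged; micro-averaging is not offered.
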