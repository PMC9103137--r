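---
title: "Selecting biomarker interactions with the multivariate gain ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting biomarker interactions with the multivariate gain ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgrselect)
```

## The problem

Many diseases are driven not by single biomarkers but by *interactions*:
subsets of biomarkers whose joint configuration determines the outcome. A
marginal screen (one variable at a time) misses a variable whose effect only
appears in combination with others — the canonical example being an
XOR-type pair, where each member is marginally independent of the outcome
while the pair determines it. `mgrselect` detects such subsets in a
discretized design matrix of `n` samples by `p` biomarkers with a binary
outcome `Y`, and builds a classifier from them.

## Influence measures

A subset $S_b$ of $k$ discrete variables partitions the samples into cells,
one per observed combination of category codes. Two scalar measures score a
partition's association with the outcome:

* **I-score**: $I(S_b) = \sum_j \left[n_1(j) - n_j \pi_1\right]^2$, where
  $n_j$ is the size of cell $j$, $n_1(j)$ its count of class-1 samples, and
  $\pi_1$ the overall class-1 proportion. It accumulates squared deviations
  of the observed case counts from their expectation under no association;
  it is unnormalized and grows with $n$.
* **Multivariate Gain Ratio (MGR)**:
  $\mathrm{MGR}(S_b) = \dfrac{Info(Y) - Info_{S_b}(Y)}{SplitInfo(S_b)}$,
  the information gained about $Y$ by conditioning on the partition,
  normalized by the partition's self-information
  $SplitInfo(S_b) = -\sum_j \frac{n_j}{n}\log\frac{n_j}{n}$. For one
  variable this is the classical Gain Ratio; the normalization counteracts
  the raw gain's bias toward subsets that induce many cells. MGR is
  invariant to the logarithm base (natural logs are used internally), and
  in the balanced two-pathway simulation below has closed forms
  ($\mathrm{GR}(X_1) = 1 - H(3/4) \approx 0.1887$,
  $\mathrm{MGR}(\{X_2,X_3\}) = (1 - H(3/4))/2 \approx 0.0944$ in any base).

Conventions for degenerate input, chosen to keep both measures total and
bounded: $0\log 0 := 0$ throughout; a partition with a single occupied cell
(zero split information) has MGR 0 — a subset that does not split the
sample carries no usable information; single-class data ($\pi_1 \in
\{0,1\}$) scores 0 under both measures rather than erroring. Counts are
exact integers; only plug-in proportions are floating point, and the gain
is clamped at zero against rounding (mutual information is non-negative,
so only floating-point error can push it below).

### Size bias of the two measures

Under a null model (all variables and the outcome iid uniform binary), both
measures still grow with subset size — pure estimation bias from the
growing number of cells. Their growth shapes differ: the I-score rises
steeply for small subsets and saturates (log-like), while MGR starts near
zero and accelerates (exponential-like). `experiment_bias_vs_order()`
reproduces this profile; the package's acceptance script recomputes the
median growth ratios. Two practical consequences:

* comparing subsets of *different* sizes by raw score is unsafe with either
  measure;
* on pure-noise subsets a backward search driven by MGR tends to retain the
  full starting subset (its bias keeps rising with size), whereas the
  I-score, being near its plateau, sheds variables more readily. Planted
  signal of realistic strength dominates both biases, so signal-bearing
  subsets are recovered cleanly under either measure.

## The selection pipeline

`mgr_fit()` composes five stages; each can also be run separately.

**Preprocessing** (`apply_preprocess`): optional intensity clamping to
`[floor, ceiling]` (defaults 100/16000), removal of low-variability
variables (post-clamp `max/min <= 5` or `max - min <= 500` by default — the
standard expression-array recipe), optional `log10`, optional univariate
prefilter (t-test or fold-change), and two-means discretization.
Discretization solves 1-D 2-means *exactly*: the optimal 2-partition of
scalar data is a threshold split, found by enumerating thresholds between
consecutive sorted distinct values and minimizing within-cluster SSE. This
removes initialization sensitivity entirely; exact SSE ties go to the lower
threshold, and the lower-mean cluster always receives code 0 so codes are
stable across runs. Constant slices are coded all-zero with a warning.
`verify_preprocessing()` dry-runs the search and classifier on a random
probe of 100 post-recipe variables and compares cross-validated accuracy
against the majority-class baseline; "reasonable" is operationalized as
baseline + 5 points (configurable), since no sharper definition is
standard. Missing values are not imputed; rows containing them are dropped
with a logged count.

**Triple screening** (`screen_triples`), engaged when `p` exceeds 100 (the
threshold is configurable; at small `p` the search needs no screening): all
$C(p,3)$ triples are scored and sorted; every 1000th score is probed and
the retained-triple count is cut where the second differences of that
subsequence first come within 1% of their maximum magnitude (the decay has
stabilized). The stride shrinks to a tenth of the triple count when fewer
than 3000 triples exist. Variables are then ranked by retention frequency
in the retained triples and cut where the first differences have stabilized
near zero *for good*: the first position from which every remaining drop is
within the larger of 1% of the maximum drop and the median remaining drop.
Requiring the whole tail (not just the current drop) to be small prevents a
flat stretch ahead of a still-pending cliff from triggering the cut; with
all frequencies equal there is no elbow and everything is kept with a
warning. Screening presumes the signal's sub-subsets are themselves
informative — a pure 3-way XOR among many nulls puts exactly one triple
above chance, which dominates the score ranking but cannot shift retention
frequencies.

**Backward-dropping search** (`run_bda`): `B` initial subsets of size `k`
are drawn uniformly; each is reduced greedily, dropping at every step the
variable whose removal maximizes the measure, and the best intermediate
subset (including the initial one) is the *return set*. Sizing guidance:
`initial_size_bounds()` reports the Poisson-approximation bound (largest
`k` with $n^2/(2\,m_{k-1}) \ge 1$, $m_{k-1}$ the cell count of $k-1$
variables) and the adequacy bound (at least 4 samples per cell on average);
any `k` between them is admissible, and the default takes the adequacy
bound. `bda_repetitions()` gives the coupon-collector estimate
$\hat B = \lceil [C(p,z)/C(k,z)] \log C(p,z)\rceil$ for covering every
$z$-subset, with $2\hat B$ as a practical upper bound. Ties are fully
specified so runs are reproducible: equal drop gains drop the smallest
variable index; equal pending scores prefer the smaller, then
lexicographically smaller, subset. Duplicate return sets are collapsed
before filtering.

**Overlap filtering and forward adding**: return sets are sorted by score
and greedily kept only if disjoint from everything kept so far (score ties
prefer the lexicographically smaller set). Each survivor is then rebuilt to
remove false positives: members are ordered by leave-one-out contribution
(score of the full set minus the set without the variable), the top
contributor seeds the rebuild, and the rest are re-admitted in that order
only if they raise the measure by more than `1e-9`. Ordering by
leave-one-out contribution rather than by single-variable score matters for
XOR-type pairs, whose members are marginally uninformative: with
single-variable ordering a noise passenger can seed the rebuild and block
the pair. The procedure itself is a reconstruction — the forward-adding
step is named but not specified in the tradition this follows — and the
strict-increase tolerance is what makes "remove false positives"
operational.

**Classification** (`fit_subclassifier`, `boost_combine`): each final
interaction of $m$ variables yields one ridge regression of the 0/1 labels
on the interaction's $2^m - 1$ singleton and product columns (for binary
codes each product is the AND of its members, which is what lets a linear
fit capture XOR; $m \le 12$ guards the blow-up). The penalty is chosen by
internal 5-fold CV on squared error over 10 log-spaced points in
$[10^{-3}, 10^3]$; fitted values at or above 0.5 classify as 1. Ridge fits
go through `MASS::lm.ridge`; zero-variance columns are dropped first (the
standardization would otherwise divide by zero), and a one-column design
uses the equivalent closed form in the same scaling convention. The
sub-classifiers are combined AdaBoost-style over the fixed pool: each round
picks the member with smallest weighted error $\epsilon$, weights it
$\alpha = \frac12\log[(1-\epsilon)/\epsilon]$ ($\epsilon$ clamped to
$[10^{-10}, 1-10^{-10}]$ so $\alpha$ stays finite at zero error), and
reweights samples toward the mistakes; rounds stop when the pool is
exhausted or nothing beats chance, falling back to the single best member
if even round one is at chance. Whether the original procedure refit
members inside boosting or weighted a fixed pool is not documented; both
exhaust the same pool here. `evaluate_cv()` re-runs the *entire* pipeline
on each training fold of a stratified 5-fold split (per-fold class
proportions within one sample of the global split), so the reported
accuracy, sensitivity and specificity include selection variability.

## The synthetic generators

`gen_module2()` is the package's benchmark: $n$ samples (default 200) of
$p$ iid uniform binary predictors (default 10), with
$Y = X_1 \bmod 2$ with probability 0.5 and $Y = (X_2 + X_3) \bmod 2$
otherwise. "mod 2" on the sum is the XOR reading, the only one consistent
with a binary outcome. It contains, by construction, a marginally visible
pathway ($X_1$) and a marginally invisible pair pathway ($\{X_2, X_3\}$);
the Bayes accuracy is 0.75. `gen_null()` draws everything iid uniform.
What these emulate is the *logical structure* of biomarker interaction
data — discrete codes, a planted subset, label noise — not the
distributional texture of real assays: no correlation between biomarkers,
no batch effects, no class imbalance, no measurement noise model. Passing
tests on them demonstrates that the machinery recovers planted structure
under its own assumptions, not that it will match any particular real
dataset's accuracy.

## Problem sizes and determinism

The test suite and acceptance script run the simulated example at its
stated conditions ($n = 200$, $p = 10$, 1000 replicates for the measure
distributions; null bias at $n = 10{,}000$ with 2000 replicates per size —
a scale at which the curve shapes are stable; 20 seeded datasets for
planted-pair recovery). Every stochastic stage takes a seed, and a fitted
pipeline derives per-stage seeds from one root seed through a fixed
fan-out, so inserting a stage never shifts another stage's stream and
identical configuration plus seed reproduces reports byte for byte.

## Known limitations

* Binary outcomes only, and discrete (or discretizable) predictors only;
  continuous-variable measures and multi-class outcomes are out of scope.
* Exhaustive triple enumeration is exact but cubic in `p`; beyond a few
  thousand variables, apply the preliminary filter first.
* MGR's size bias means raw MGR values of large subsets are not comparable
  with small ones; within the backward search this surfaces as full
  retention of pure-noise starting subsets. Overlap filtering and forward
  adding remove most of these, but on data with no signal at all the
  selected "interactions" are necessarily noise — `verify_preprocessing()`
  against the majority baseline is the guard.
* The boosting and forward-adding procedures are reconstructions of steps
  that their originating tradition names but does not specify; both are
  documented above and fixed by explicit tie rules and tolerances.
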