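---
title: "Measuring metacognition with mutual information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring metacognition with mutual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaI)
```

## The measurement problem

In a typical confidence experiment a subject makes a binary decision about
a stimulus (`d = ±1`, response `a = ±1`) and rates their confidence `c`
that the decision was correct.  Conceptually the subject splits into an
*actor* (the decision) and a *rater* (the confidence).  Three properties
of the rating are of interest: *bias* (overall miscalibration),
*sensitivity* (trial-by-trial covariation of confidence with accuracy
`r = 1{d = a}`), and *efficiency* (sensitivity corrected for how easy the
rating problem is — a rater attached to a near-perfect actor has almost
nothing to predict).

The model-based route to sensitivity — meta-d′ — asks what type-1
sensitivity an imaginary first-order observer would need for its
confidence statistics to match the data, and normalizes by the actor's
actual d′ (the M-ratio).  That construction assumes ratings are monotone
in accuracy and inherits any misfit of the assumed observer.  This package
implements the information-theoretic alternative.

## meta-I and its two efficiency ratios

For a joint distribution `P(r, c)` over accuracy and binned confidence,

$$\mathrm{meta}\text{-}I = H_2(r) - H_2(r \mid c), \qquad
  H_2(r) = h_2(P(r=1)), \quad
  H_2(r \mid c) = \sum_c P(c)\, h_2(P(r=1 \mid c)),$$

with `h2` the Bernoulli entropy in bits ([binary_entropy()]; `0 log 0 = 0`,
empty bins carry zero weight).  Mutual information is symmetric, label
invariant (only the conditional accuracy a level affords matters, not its
name or order), and obeys the data-processing inequality: merging bins can
only lose information, so the measure grows — as a sensitivity measure
arguably should — with the number of well-used rating levels.  All
quantities are reported in bits and printed to 3 decimals by default.

Two normalizations turn sensitivity into efficiency:

* `meta_I1r = meta_I / meta_I_dprime(d_prime)`: the denominator is the
  mutual information achieved by an ideal first-order Bayesian rater at
  the actor's d′ — evidence $\alpha \sim N(d\,d'/2, 1)$, decision by sign,
  confidence $c = 1/(1+e^{-d'|\alpha|})$, which is the exact posterior
  probability correct.  The rater in the denominator has continuous
  confidence; a matched-granularity variant
  (`meta_I_dprime_binned(d_prime, b)`) is available as an explicit opt-in,
  since an empirical rater restricted to `b` levels may deserve a
  `b`-level yardstick.
* `meta_I2r = meta_I / accuracy_entropy(d_prime)`: normalization by the
  upper bound $H_2(r)$ gives an absolute efficiency in $[0, 1]$,
  appropriate when the rater may know *more* than the actor (then the
  actor's d′ is no yardstick at all).

The display equation for the first-order rater admits two readings —
evidence with unit variance and means $\pm d'/2$, or means $\pm 1$ and
standard deviation $2/d'$.  We implement the unit-variance form, under
which the logistic confidence is exactly the Bayesian posterior; because
mutual information is invariant to strictly monotone transforms of the
conditioning variable, the continuous normalizer is identical under both
readings, and the test suite verifies this equivalence by quadrature on
both parameterizations.  `meta_I_dprime()` integrates
$H_2(r) - E_\alpha h_2(P(\text{correct}\mid\alpha))$ over the two-component
Gaussian mixture by adaptive quadrature spanning ±8 sd around both means
(absolute tolerance well below $10^{-4}$ bits).  The curve rises with d′
at low sensitivity and falls at high sensitivity, where there is little
accuracy entropy left to explain — one reason a single normalizer cannot
serve all regimes.

## Binning continuous confidence

meta-I is computed on discrete ratings.  Nearly continuous scales (slider
reports) are quantized by a `binning_scheme`: thresholds
$t_1 < \dots < t_{b-1}$ defining half-open bins
$[lo, t_1), \dots, [t_{b-1}, hi]$, boundary values going up, matching the
usual printed interval notation.  `optimize_thresholds()` maximizes meta-I
over threshold placements.  Candidates are midpoints between consecutive
distinct observed confidences, thinned to at most 200 (configurable)
evenly through the sorted list; the search is exhaustive for `b ≤ 3` and
greedy coordinate ascent with a seeded 10-start multi-start for larger
`b`, with objective ties broken toward the lexicographically smallest
threshold vector so results are deterministic given the seed.  The same
weighted optimizer runs on observed trials, on the first-order model's
exact bin masses, and on the second-order model's quadrature nodes, so
data and theory are optimized by identical machinery.

Optimization is in-sample: with few trials and many bins the optimized
meta-I inherits selection bias on top of the plug-in bias discussed next,
and thresholds are not cross-validated.  `granularity_curve()` reports the
ratio of optimized meta-I at `b` bins to that at 2 bins; on the model
surface this is provably ≥ 1 and non-decreasing, and on data it shows how
many levels a subject actually uses to good effect.

## Correcting plug-in bias

Plug-in mutual information is biased upward in finite samples.  Rather
than analytic corrections, `permutation_corrected_meta_I()` shuffles the
confidence column against the accuracy column — preserving both marginals
exactly — and subtracts the null mean from the raw estimate (both are
always reported).  The default is 1000 seeded permutations; within-response
shuffling preserves the conditioning of response-specific measures.  An
exact mode computes the null mean without sampling by enumerating all
tables with the observed margins under the multivariate hypergeometric
law, refusing (with a pointer to randomized mode) when the enumeration
would exceed a configurable cap.  Corrected values can be negative; they
are flagged but not clipped, since clipping would bias averages across
subjects.

## The second-order observer

To study the measures where ground truth is known we implement a
second-order generative model.  Per trial, with $d = \pm 1$ equiprobable
and independent standard normal noises:

$$\alpha = d + A\epsilon_\alpha \;(A = 2/d'), \qquad
  \beta = \alpha + B\epsilon_\beta, \qquad
  \gamma = d + \sqrt{G^2}\,\epsilon_\gamma.$$

The actor responds with the sign of $\alpha$ (ties, a measure-zero event,
to +1).  The rater sees $(a, \beta, \gamma)$: a noisy read-out of the
actor's evidence plus unique (e.g. post-decisional) information about the
stimulus itself, and reports the exact posterior
$c = P(a = d \mid a, \beta, \gamma)$, computed in closed form: for each
$d$, $P(a, \beta \mid d)$ is a Gaussian density in $\beta$ times the
normal-posterior tail probability of $\alpha$'s sign, and $\gamma$
contributes an independent Gaussian likelihood.  We evaluate the posterior
on the log scale, so it remains defined arbitrarily far into the tails.

We parameterize the unique signal by its noise *variance* `g2` $= G^2$
(argument `b_noise` is the read-out noise sd).  The variance is the
natural scale on which the rater's information quality is compared and
swept, and it is the parameterization under which the package's reference
cases — `g2 = 5` (weak unique signal: meta-I ≈ 0.104 bits, meta-I1r ≈ 2,
meta-I2r ≈ 0.12, meta-d′ ≈ 1.75) and `g2 = 0.5` (strong unique signal:
meta-I ≈ 0.620, meta-I2r ≈ 0.70, meta-d′ ≈ 4.52), both at d′ = 1, B = 1,
bins 0.1/0.5/0.9 — take their standard values.  Limits:
`b_noise → 0, g2 → ∞` recovers the first-order rater (meta-I1r → 1, the
analogue of M-ratio 1), verified in the tests; `b_noise → ∞, g2 → 0`
approaches a rater with perfect error knowledge (meta-I2r → 1).

Expected measures are computed by tensor-grid trapezoid quadrature over
$(\beta, \gamma)$, by default 801 × 801 nodes spanning ±8 marginal sds
(both configurable); per-bin mass is accumulated by evaluating the
confidence surface at each node, and because the confidence is the true
posterior, a bin's conditional accuracy is its mass-weighted mean
confidence.  The raw mass is checked against $P(a) = 1/2$ and a deficit
beyond `mass_tol` ($10^{-4}$) is an error rather than a silent
renormalization.  At these defaults the quadrature is accurate to well
under $10^{-3}$ bits on meta-I; parameter sweeps (`sweep_measures()`) use
401 or 301 nodes per dimension, adequate for their qualitative summaries
at a fraction of the cost.  `simulate()` draws trials from the same model,
bit-reproducibly given a seed, and the suite confirms Monte-Carlo and
quadrature agree (at $10^6$ trials, within 0.01 bits).

## The meta-d′ reference fitter

For comparison, `fit_meta_d()` implements the classical equal-variance
Gaussian type-2 fit: a notional first-order observer with sensitivity
meta-d′, its type-1 criterion rescaled by meta-d′/d′, and strictly ordered
type-2 criteria per response side (parameterized as cumulative positive
increments).  Counts are fitted by maximum type-2 likelihood; expected
probabilities (e.g. from `expected_bin_stats()`) by cross-entropy
minimization, which is the same objective at infinite data.  The search is
a bounded golden-section scan over meta-d′ with nested quasi-Newton (then
simplex-polished) criteria optimization — deterministic, no random
restarts.  Count input receives a small configurable pseudo-count
(default `1/(2b)`) against empty cells; probability input none.  Fitting
statistics generated by a first-order observer recovers meta-d′ to three
decimals across d′ and granularities (M-ratio = 1), and the fitted
cross-entropy reaches the generating entropy floor to $10^{-6}$.
Unlike meta-I, the fit changes when bin order is scrambled — the tests
assert this contrast explicitly.

## What the synthetic generator does and does not show

The second-order simulator is the package's test bed: it produces data
with known exact measures, spanning hypo- to hyper-efficiency as `g2`
falls.  It emulates a stationary observer — fixed d′, unbiased actor,
equal-variance evidence, perfectly calibrated confidence with unlimited
report precision.  Real data violate most of these at least mildly:
ratings are coarse and lapse-prone, criteria drift, evidence strength
varies across trials, and confidence is reported with noise.  Passing the
suite therefore certifies the estimators and the model mathematics, not
robustness to such misspecification; the measures themselves (meta-I on
binned counts, the permutation correction) make no stationarity
assumption beyond exchangeability under the null.

## Degenerate inputs and conventions

Logarithms are base 2 throughout.  Counts are normalized once at table
construction; an optional additive smoothing constant (default 0) exists
for degenerate cells but is never applied silently.  All-correct data, or
a single occupied bin, yield meta-I = 0 with a structured warning rather
than an error; response-specific measures require both responses present,
else the stratum is flagged absent.  `d′ ≤ 0` is an error wherever a
normalizer would be undefined.  Stored accuracy columns are ignored and
recomputed from stimulus and response on input.

## Known limitations

* Continuous (unbinned) mutual-information estimation is out of scope;
  confidence is always binned, and estimates carry the corresponding
  quantization loss by design.
* Threshold optimization is in-sample (no cross-validation).
* The meta-d′ fitter covers the unbiased equal-variance case with a
  shared meta-d′ across response sides; response-specific meta-d′,
  unequal-variance and hierarchical variants are not implemented.
* Biased actors (type-1 criterion far from 0) are handled by the meta-d′
  fitter but the first-order normalizer of meta-I1r assumes an unbiased
  actor.
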