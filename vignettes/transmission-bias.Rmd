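---
title: "Modelling meiotic transmission of independently segregating elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling meiotic transmission of independently segregating elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iseseg)
```

## The biological problem

Some rotifer clones carry Megabase-sized independently segregating genomic
elements (ISEs) — supernumerary, B-chromosome-like blocks of largely
satellite DNA that have no pairing partner at meiosis. A mother with `n`
ISEs produces haploid males carrying anywhere from 0 to `n` of them, so the
males of a clone fall into `n + 1` discrete genome-size (GS) classes. If
segregation were a fair coin per element, class frequencies would be
Binomial(`n`, 0.5). Deviations from that null carry information about
meiotic drive (an element reaching the egg pole too often), drag (the
opposite), and interactions between elements. `iseseg` models those
deviations, estimates them from flow-cytometry data, and tests them.

## The segregation model

The model assigns each of the `2^n` pole configurations (every ISE to the
egg pole or the polar-body pole) an unnormalised weight built from two
parameters:

* **transmission bias** `tb` — each ISE contributes a marginal factor
  `1 + tb` if it heads to the egg pole and `1 - tb` otherwise. `tb` is
  dimensionless in `(-1, 1)`; the single-element transmission rate is
  `(1 + tb)/2`, so `tb = 0.1` means a rate of 0.55 (mild drive) and
  negative values mean drag.
* **cosegregation bias** `cb` — every unordered pair of ISEs contributes
  `1 + cb` if the two end up at the same pole and `1 - cb` if they split.
  Negative `cb` ("repulsion") pushes pairs to opposite poles; `cb = -1`
  would reproduce the strictly disjoint segregation of a regular
  chromosome pair.

Outcome probabilities are these weights normalised over all `2^n`
configurations, and the class-`k` frequency is the summed probability of
configurations with `k` ISEs at the egg pole. Because ISEs are exchangeable
in this law, the weight depends on a configuration only through `k`:

```
w(k) = C(n, k) (1+tb)^k (1-tb)^(n-k) (1+cb)^(C(k,2)+C(n-k,2)) (1-cb)^(k(n-k))
```

`class_distribution()` evaluates this collapsed form; the test suite checks
it against brute-force summation of `outcome_weight()` over all pole
vectors, and `simulate_segregation()` provides a third, sampling-based
route. Useful limits, all tested: `cb = 0` collapses to
Binomial(`n`, `(1+tb)/2`); `tb = 0` gives a distribution symmetric in
`k` and `n - k`; `n = 2, tb = 0, cb -> -1` concentrates all mass on the
single-ISE class.

The pairwise multiplicative form is a design choice: with more than two
elements, a two-parameter description cannot single out one joint law, and
we adopt the product over all pairs because it reproduces the known
two-element behaviour exactly (O/E ratios `0.7 / 1.3 / 0.7` at
`cb = -0.3`), degrades smoothly to the binomial null, and treats elements
exchangeably. Whether `cb` acts "before" or "after" `tb` mechanistically is
not distinguishable from class frequencies, so the model makes no claim
about ordering. Exact enumeration is capped at `n = 12` (the clones of
interest carry at most about five resolvable ISEs); beyond the cap the
Monte-Carlo simulator is the intended tool.

Observed/expected (O/E) ratios divide each class frequency by the unbiased
Binomial(`n`, 0.5) expectation. They are a display transform, not the
fitting target: a monotone O/E trend signals drive or drag, depressed
extremes signal negative cosegregation.

## Parameter estimation

`grid_fit()` evaluates the model on a regular grid over
`tb, cb in [-0.95, 0.95]` and minimises the root-mean-square error between
predicted and observed class frequencies. Choices that were genuinely open:

* **Grid step 0.05** (39 x 39 grid). The grid range is part of the method
  (the boundary `|cb| = 1` puts zero weight on every configuration once
  `n >= 3`); the step is ours, matching the precision at which estimates
  are interpretable given typical sample sizes.
* **RMSE on frequencies, not O/E ratios.** Frequencies are the model's
  output; O/E rescales residuals by `1/expected`, which would overweight
  the rare extreme classes.
* **Tie-breaking** towards the smallest `|tb| + |cb|`, then
  lexicographically — the most parsimonious deviation from unbiased
  segregation, and deterministic.
* **One ISE:** `cb` never enters the likelihood of a two-class clone, so it
  is reported as `NA` rather than a misleading 0.
* **Replicates:** per-clone frequencies entering the fit are the mean of
  replicate samples (the pooled-replicates alternative is available by
  concatenating counts before normalising).

Recovery behaviour (all under test): exact recovery, with zero RMSE, of any
grid-point truth; recovery within one grid step from 5 x 10^4-male
multinomial samples; median error shrinking as males grow from 10^3 to
10^5.

## Decomposing fluorescence histograms

Flow cytometry gives, per sample, a one-dimensional cloud of fluorescence
areas: male GS-class peaks between roughly 30 and 70% of the diploid female
internal-standard peak, the female peak itself, and debris. `iseseg`
recovers class proportions by finite-mixture fitting:

* `fit_finite_mixture()` runs expectation-maximisation for every component
  count `g` in `[g_min, g_max]` (defaults 3-8) and keeps the lowest-BIC
  fit. `g_max` deliberately exceeds the class count: surplus components
  soak up background and asymmetry, which improves class resolution. The
  EM convergence tolerance (1e-5 relative log-likelihood) and iteration cap
  (1000) are the conventional settings for this procedure.
* **Family.** The default component is the skew-normal; a plain normal
  family is available. Skewness here absorbs an instrument artifact
  (asymmetric peak tails), not a biological claim. We did not implement
  skew-t tails: the heavy-tail refinement mainly reshuffles weight between
  a peak and the debris pool, which our explicit background handling
  already does, and it adds a degrees-of-freedom estimation with poor
  identifiability at these event counts. On synthetic Gaussian-ish peaks
  the skew-normal is an exact superset of the truth.
* **Initialisation** is a deterministic quantile split of the sorted
  events (equal-count blocks; block skewness seeds the shape sign), so a
  fit is a pure function of the data and settings. Random restarts are
  used only if a component degenerates (scale collapse or emptied weight),
  are seeded, and are bounded; with the quantile initialisation they are
  rarely triggered. The EM inner loop is compiled (C++) with an erfc-based
  log-CDF; the test suite pins it against `stats::pnorm` and, for the
  normal family, against an independent EM implementation (`mclust`).
* `assign_components_to_classes()` maps each fitted component to the
  nearest expected class position — the clone's male genome sizes scaled
  to the female peak in the same sample — within a +/-5% window, merges
  same-class components (weights summed, weight-weighted mean position),
  and labels everything else background; a component with weight below
  0.02 and scale above three times the median in-class scale is background
  even inside a window. The window and the broad-component rule are
  declared conventions: no published criterion exists. Classes closer than
  twice the window raise an error — such clones (in practice, very high
  ISE numbers) produce continuous GS distributions that should be
  summarised as densities, not forced into classes.
* `renormalize_classes()` drops background and rescales proportions to
  sum to one.

Quality control follows the standard instrument criterion: the coefficient
of variation of the female internal-standard peak, with samples above 3.5%
flagged for exclusion (observed instrument range runs to about 4%). The
pipeline reports exclusions rather than silently dropping samples.

## Count reconstruction and G-tests

Proportions are turned back into integer male counts with
largest-remainder (Hamilton) rounding — the rounding rule is unstated in
the field, and Hamilton is the choice that perturbs proportions least while
guaranteeing the counts sum to the number of males; ties go to the lower
class index for determinism. `repeated_g_test()` implements the replicated
goodness-of-fit decomposition: total G (sum over replicates, df summed),
pooled G (on summed counts), heterogeneity G (total minus pooled), with
`total = pooled + heterogeneity` holding exactly for both G and df — with
`r` replicates and `k` classes the heterogeneity df is `(r-1)(k-1)`. The
plain G statistic `2 * sum(O ln(O/E))` is the default; the Williams
correction is available but off, since the decomposition identity is exact
only for the uncorrected statistic. Null calibration (pooled type-I error
near the nominal 5% under multinomial sampling) is part of the test suite.

## What the synthetic generator does and does not emulate

`sim_config()` / `simulate_clone_sample()` generate every input the
pipeline consumes: multinomial male counts from the segregation model,
Gaussian class peaks at the karyotype's relative genome sizes (CV default
2.5%, the middle of the observed 1.7-3.95% instrument range), a female
internal-standard peak, and uniform debris over 0.2-1.2 times the female
channel (default 5% of events). Defaults pool 200 males per sample, the
experimental ceiling. Total male events per sample (default 8000) are a
convention — each male contributes many stained nuclei, and published
protocols do not state an events-per-male rate — and are allocated to
classes in proportion to the simulated male counts. Stage series
(`sync` / `accum` / `hatched`) share one truth unless per-class viability
weights are configured, which is how class-dependent embryonic survival is
emulated; `simulate_hatching_table()` generates egg-level Bernoulli
outcomes with a male-specific genome-size slope on the logit scale.

Deliberately not emulated: skewed or heavy-tailed instrument peaks (the
generator's peaks are Gaussian; the fitting family is more general),
doublets and gating artifacts (inputs are taken as already gated),
non-uniform debris spectra, and drift of the fluorescence scale within a
sample. Passing recovery tests on these synthetics therefore demonstrates
correctness of the estimation machinery under realistic noise levels and
class spacings — not robustness to every instrument pathology in real
exports.

## Numerical and scale choices

Frequencies are validated to sum to 1 within 1e-8 on input and 1e-12 in
model output. Events are standardised before EM and parameters mapped
back; log-likelihood and BIC are reported on the original scale. The test
suite and examples run at reduced but statistically meaningful sizes —
10^5 males for Monte-Carlo/enumeration agreement (4 standard errors),
5 x 10^4 males and 3500-6000 events for full-loop recovery, 1000
simulations for G-test calibration — sizes chosen so every documented
property is exercised with comfortable statistical margins.

## Known limitations

* The two-parameter law is one consistent realization of "pairwise
  cosegregation"; other joint laws agreeing at `n <= 2` could diverge at
  `n >= 3`.
* Grid-search least squares reports no confidence intervals; the surface
  (`tidy()` on a fit) is the honest uncertainty display.
* Class-based analysis assumes ISEs of roughly similar size per clone;
  unequal sizes shift peak positions (handled) but can in principle make
  distinct carried-subsets overlap in genome size (not modelled).
* Clones whose classes are unresolvable (spacing under twice the matching
  window) are refused by the class mapper by design; analyse them as
  continuous densities instead.
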