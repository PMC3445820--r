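---
title: "Methods: two-sample tests on skewed, spread-unequal distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample tests on skewed, spread-unequal distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(skewsim)
```

## The model

`skewsim` studies a deliberately minimal two-sample world. Each scenario is
a pair of continuous distributions (X, Y) from one family — gamma or
lognormal — constrained so that

* both members have the **same coefficient of skewness**
  γ₁ ∈ {1, 2, 3, 4} (the standardized third central moment, not a
  quantile-based measure: that choice matches the closed forms
  γ₁ = 2/√k for a gamma with shape k, and γ₁ = (w + 2)√(w − 1),
  w = exp(σ²), for a lognormal with log-scale σ);
* both members have **exactly the same mean**;
* the **only** difference is spread: SD(X)/SD(Y) = ρ ∈ {1.05, …, 1.50}.

Under these constraints the Welch t-test's null hypothesis (equal means) is
*true* in every scenario, while the Wilcoxon-Mann-Whitney (WMW) test's
general null, P(X < Y) = 1/2, is *false* whenever ρ > 1. Every simulated
rejection rate therefore has a clean interpretation: type-I error for the
t-test, power against P(X < Y) ≠ 1/2 for the WMW test.

## Parametrization: equal means, not equal medians

A shared skewness forces a shared shape parameter (k or σ). Given that,
equal means and equal medians cannot *both* hold once the SDs differ: the
location shift that equates means does not equate medians (the gap is
O((ρ − 1)·|mean − median|), a few percent of an SD at ρ = 1.5). The package
equalizes **means exactly** and lets medians differ slightly.

The reasons, in order of weight:

1. The simulated t-test rejection rates sit at the nominal level across the
   whole grid. That is the signature of exactly equal means; under
   equal-medians matching the t-test would drift off its level at large n.
2. The published stochastic-superiority table is reproduced cell-for-cell
   (to the printed 2 decimals, with a one-ulp rounding ambiguity in a
   couple of cells) by the equal-means construction — see the acceptance
   suite.

The convention is: Y is the unshifted reference with SD normalized to 1; X
shares Y's shape, has scale ρ·scale(Y), and is shifted *down* so that the
means coincide. X's support therefore starts slightly below Y's; both tests
are location-family agnostic, so this choice only fixes reproducibility,
not results. Shifting Y (or both) instead would change nothing detectable
by either test.

## P(X < Y) by quadrature

`prob_x_less_y()` evaluates ∫ f_X(t){1 − F_Y(t)} dt. Numerically the
integral is computed after the substitution u = F_X(t):

∫₀¹ {1 − F_Y(Q_X(u))} du,

whose integrand is bounded, smooth, and monotone on [0, 1]. This sidesteps
the endpoint singularity of gamma densities with shape < 1 (every skewness
above 2 in the grid), which makes naive t-space quadrature fragile. The
unit interval is cut at fixed breakpoints concentrated near 0 and 1 and
each piece is handed to the adaptive Gauss-Kronrod rule with a summed
absolute-error budget of 1e-8 — comfortably below the 2 printed decimals of
any displayed probability and checked against (i) a frozen independent
t-space quadrature oracle at 1e-7 and (ii) paired Monte Carlo draws for all
64 grid pairs at 3 MC standard errors.

Root-finding for the lognormal σ brackets w = exp(σ²) on (1 + 1e-12, 1e6)
— covering skewness up to well beyond 100 — and polishes to machine
tolerance; skewness 4 has the exact root w = 2, used as a unit-test anchor.

## The two tests

Both are implemented from first principles; `stats::t.test()` and
`stats::wilcox.test()` appear only as oracles in the test suite.

**Welch t**: unbiased sample variances, fractional Welch-Satterthwaite df
(never rounded), two-sided p from Student's t. Degenerate input (both
variances zero) yields p = 1 when the means agree and p = 0 otherwise,
flagged rather than silently dropped.

**WMW**: Mann-Whitney U from midranks of the pooled sample; two-sided p
from the normal approximation with a 0.5 continuity correction and the
tie-corrected variance. The simulated data are continuous, so ties have
probability zero and all simulated n are ≥ 10, where the approximation
error against exact enumeration is below 0.02 (property-tested at
n₁ = n₂ = 8, the worst case the exact mode covers comfortably); this
matches the default behaviour of the major statistical packages for
samples of this size. Exact enumeration over all C(n₁+n₂, n₁) assignments
is retained for n₁ + n₂ ≤ 16 as the small-sample oracle. At the n = 10
grid margin the two modes were checked to give indistinguishable rejection
rates and p-value-comparison proportions at Monte Carlo resolution, so the
normal approximation is used uniformly.

The rejection rule is strict, reject iff p < α, and the p-value comparison
is strict as well: "WMW p smaller" means p_WMW < p_t, with ties (a
measure-zero event) counted as not smaller — the conservative reading.

## The Monte Carlo engine

A scenario is (family, γ₁, ρ, n, α = 0.05, R = 10,000, seed). Replicates
are processed in blocks capped at ~2·10⁶ draws for memory, but the base
draws are laid out so the random stream is consumed in exactly the order of
a sequential run (n draws for X, then n for Y, replicate by replicate) —
block size can never affect a result, which the suite verifies against a
loop over the public one-sample API.

Per-scenario seeds are derived from a master seed by a polynomial hash of
the scenario key folded through a multiplicative congruential step modulo
2³¹ − 1. Consequences: any cell can be recomputed in isolation; grid
execution order is irrelevant; the 448-cell design gets 448 distinct
streams.

Each proportion p̂ is reported with its binomial Monte Carlo standard error
√(p̂(1 − p̂)/R); at R = 10,000 that is ≤ 0.5 percentage points. Stochastic
reproduction targets are accepted within 3 *combined* standard errors
(both sides treated as 10,000-replicate estimates).

## What the generator does and does not emulate

The generator *is* the stated world: smooth unimodal skewed laws, exact
mean equality, spread differences of 5–50 %, independent equal-sized
groups. Real clinical data add features deliberately outside this world:
ties and discreteness (rank ties change the WMW variance), outliers and
contamination, unequal group sizes, dependence, and mean differences that
are not exactly zero. A green suite therefore establishes the *mechanism*
— the WMW test's sensitivity to spread under skewness — not a quantitative
claim about any particular dataset.

## Numerical and design choices

* Quadrature: u-space piecewise adaptive integration, abs. tol. 1e-8;
  upper tails enter through Q_X(u), never through explicit truncation.
* Root-finding: relative tolerance at machine precision after bracketing.
* Display rounding is round-half-even (R's default) and cosmetic only;
  CSV/JSON outputs carry 17 significant digits and round-trip losslessly.
* Config files are a flat `key: value` mapping (a YAML subset) parsed
  internally, keeping the runtime dependency set to `jsonlite` +
  `optparse`.
* The exact-enumeration WMW mode is capped at n₁ + n₂ ≤ 16 (12,870
  assignments); beyond that the normal approximation is already inside
  0.02 everywhere and the mode would only be an attractive nuisance.
* Degenerate replicates cannot occur for continuous families except by
  floating-point underflow; if one ever appears it is counted under the
  documented p-value conventions and a warning names the scenario.

## Known limitations

* Only gamma and lognormal families; no mixtures or contamination models.
* Median-matching is not offered as an alternative parametrization; the
  package's scope is the equal-means world described above.
* The WMW normal approximation is used down to n = 10; users running
  *smaller* groups should prefer `method = "exact"`, which the engine does
  not currently select automatically.
* The engine is single-threaded; the seeding scheme is parallel-safe, but
  parallel dispatch is left to the caller.
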