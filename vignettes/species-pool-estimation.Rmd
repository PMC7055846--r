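---
title: "Estimating species pools from multi-site inventories"
author: "faunest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating species pools from multi-site inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faunest)
```

## The problem

A biodiversity inventory — for instance a national network of Malaise traps
processed by taxonomic experts — observes only part of the regional species
pool. Rare species are missed, and species restricted to unsampled places
are invisible no matter how hard the sampled sites are worked. `faunest`
estimates the total pool size per taxonomic group from the structure of the
observed data, and quantifies when such estimates can be trusted.

Two families of information are exploited:

* **Rarity counts.** The numbers of species observed exactly once or twice
  (singletons `F1`, doubletons `F2` on specimens; uniques `Q1`, duplicates
  `Q2` on sites) drive the classical non-parametric extrapolations (Chao1,
  Chao2, ACE, jackknife, bootstrap) and the Preston lognormal fit.
* **Prior knowledge.** Where a pre-inventory checklist exists, the share of
  already-known species in the new catch acts like the share of marked
  animals in a recapture sample (Chapman mark-recapture).

## The combined non-parametric estimator

The Chao2-type across-site extrapolation

$$\hat S = S_{obs} + \frac{Q_1 (Q_1 - 1)}{2 (Q_2 + 1)}$$

accounts for heterogeneity across sites, but its inputs $Q_1, Q_2$ are
themselves underestimated when individual sites are undersampled: more
trapping at the same sites would reveal more of the locally rare,
geographically restricted species. The combined estimator assumes that the
*proportion* of uniques and duplicates among a site's species would stay
roughly constant under deeper sampling there. Each site's observed uniques
$U_i$ and duplicates $D_i$ are therefore scaled up by the site's own
Chao1-type correction $e_i = F_1^{(i)}(F_1^{(i)} - 1) / (2(F_2^{(i)} + 1))$:

$$\hat S_1^{(i)} = U_i + e_i \frac{U_i}{S_{obs}^{(i)}}, \qquad
  \hat S_2^{(i)} = D_i + e_i \frac{D_i}{S_{obs}^{(i)}},$$

summed into $\hat Q_1 = \sum_i \hat S_1^{(i)}$ and
$\hat Q_2 = \frac12 \sum_i \hat S_2^{(i)}$ (real-valued, never rounded),
which replace $Q_1, Q_2$ in the across-site step. Key assumptions:

* within-site sampling is incidence-like enough for the Chao1 correction to
  apply at the site level (abundance counts per site are required — the
  estimator refuses incidence-only input);
* undiscovered species at a site are uniques/duplicates in the same
  proportion as the discovered ones;
* sites with no specimens carry no information and are excluded before the
  across-site step (the matrix container already drops them).

Because $\hat Q_1$ is either 0 or at least 1, the final estimate can never
fall below $S_{obs}$, and when no within-site singletons and no cross-site
uniques exist every correction vanishes and the estimator collapses to
$S_{obs}$.

### Denominator convention

Printed forms of these equations are typographically ambiguous between
$2F_2 + 1$ and the standard bias-corrected $2(F_2 + 1)$. The package
defaults to the bias-corrected reading — the form defined for small samples,
consistent with the `2(F2+1)` Chao1 and `2(Q2+1)` Chao2 defaults — and
exposes the literal reading via `denominator = "as_printed"` (and
`variant = "classic"` for the uncorrected $F_1^2/2F_2$ Chao forms). The
worked examples in the test suite pin both conventions against a
brute-force per-site oracle.

## Chapman mark-recapture

With $S_{known}$ checklist species, $S_{obs}$ observed species and
$S_{obs,known}$ of them previously known,

$$\hat S_{MR} = \frac{S_{obs} + 1}{S_{obs,known} + 1}(S_{known} + 1) - 1,$$

defined even when nothing was known beforehand. Reported values are rounded
to the nearest integer with ties half-up, which reproduces the published
per-group inventory estimates exactly; the unrounded point is retained.
Assumptions: known and unknown species are equally catchable, and the pool
is static over the sampling period. The estimator accepts tallies or raw
species lists (overlap computed by exact label matching after trimming — no
fuzzy name reconciliation).

## Data model

Records are read from delimited text (comma or tab, auto-detected; column
roles supplied as a mapping, not fixed names). Two filtering rules are
applied before estimation: records determined only to genus level (taxon
label ending in an unqualified `sp.`) are removed with a logged tally, and
`sp. indet.` records are kept as distinct species. Zero-count records are
dropped with a warning. Samples are pooled to the trap/site level before
estimation — the site-indexed equations and site-order accumulation curves
both treat the trap as the sampling unit; pooling per trap-year instead is
possible by recoding the site column upstream. Groups with any
incidence-only record are demoted wholesale to incidence matrices (with a
warning when abundance and incidence records are mixed), on which only the
incidence-based estimators run.

## Accuracy metrics and the benchmark

Accuracy is measured on the natural-log scale: squared error
$(\ln \hat S - \ln S)^2$ and bias $\ln \hat S - \ln S$. Natural logs make a
squared error of 0.4 correspond to a multiplicative error factor
$\exp(\sqrt{0.4}) \approx 1.9$ — the estimate may be off by nearly half or
double. `benchmarkEstimators()` takes true richness as *data* (an expert
total or a prior checklist size), never computes it, and by default excludes
datasets with $\le$ 100 specimens or $\le$ 5 sites, where the rarity counts
are too unstable to be diagnostic.

## The synthetic community generator

`simulateCommunity()` emulates a large heterogeneous region sampled by a
modest number of traps:

* **Pool and abundances.** `poolSize` species with lognormal relative
  abundances, default `sdlog = 1.5` — a steep abundance distribution in
  which a handful of species dominate the catch, as is typical of
  flight-intercept trapping.
* **Occupancy (the heterogeneity knob).** By default each species occupies
  a random subset of sites, independent Bernoulli with mean occupancy 0.3,
  producing realistic mixtures of uniques and duplicates without tuning;
  `list(type = "fixed", k)` and per-species probability vectors are
  available, and `p = 1` gives the homogeneous all-species-everywhere case.
* **Sampling.** Per-site counts are independent Poisson draws with rates
  proportional to abundance × occupancy, normalised within each site so the
  expected site total equals the site's `effortPerSite`. The Poisson choice
  makes binomial thinning (`subsampleMatrix()`, emulating partial processing
  of the catch) and the effort algebra exact, and yields the closed form
  $E[S_{obs}] = \sum_k (1 - e^{-\lambda_k})$ used as a test oracle. A
  fixed-total multinomial draw would differ negligibly (63.2 vs 63.4
  expected species in the 100-species, effort-100 reference case).
* **Seeds** are mandatory in the spec object and never touch the global RNG
  stream.

What the generator does *not* emulate: spatial autocorrelation between
sites, temporal turnover within the sampling period, taxonomic
misidentification, and abundance distributions fitted to any real
inventory. Passing benchmarks on these communities therefore shows that the
estimators behave as designed under controlled heterogeneity and
undersampling — not that their point estimates are unbiased for any
particular real fauna.

### Benchmark design used in the acceptance tests

Coverage of the pool ($S_{obs}/S$) is swept from roughly 10% to 100% the way
real inventories vary: with the pool size, the number of traps, and the
per-trap effort. The seeded design uses seven tiers, from 500-species pools
sampled by 6 traps at 20 specimens each (coverage ≈ 0.1–0.2) up to
150-species pools sampled by 16 traps at 5000 specimens each (coverage ≈ 1),
450 communities in total — small enough to run in seconds, large enough
that bin means are stable. On these communities the pooled-sample Chao1 is
strongly negatively biased at low coverage, Chao2 less so, and the CNE least
(at the price of higher variance), and the mean squared log error of all
three declines monotonically across the coverage bins <20%, 20–50%, 50–80%,
>80%.

## Accumulation curves and permutation tests

`accumulationCurve()` averages the distinct-species count over random
permutations of the site accumulation order (default 10,000; a single
seeded generator), with 2.5%/97.5% permutation quantiles as a band. The
mean converges to the exact hypergeometric expectation, which the tests
verify by exhaustive enumeration on up to 5 sites.

`permutationTest()` compares a compositional statistic across an ordered
site grouping against the distribution obtained by permuting the
site-to-group assignment. The statistic had to be chosen: the default is
the difference in the focal-trait proportion between the last and first
group along the stated ordering (`"extreme_diff"`), one-sided in the
observed direction; a least-squares slope of the proportions on group rank
(`"trend"`) is the alternative, and sidedness is configurable. Monte-Carlo
p-values use the add-one convention $p = (1 + \#\{null \ge obs\})/(n+1)$,
which can never return 0; `exhaustive = TRUE` enumerates all distinct
assignments instead and returns the exact proportion. Under a simulated
null the Monte-Carlo p-values are uniform (checked by a Kolmogorov–Smirnov
test over 500 seeded runs).

## Numerical choices

* **Rounding of reported estimates**: nearest integer, ties half-up
  (`floor(x + 0.5)`), matching published inventory tables; never applied to
  intermediate quantities.
* **Preston fit**: abundances are binned into half-open log2 octaves with
  counts lying exactly on an octave boundary split 50/50 between the
  adjacent octaves; a Gaussian is fitted to octave frequencies by nonlinear
  least squares, initialised from a log-quadratic regression (moment
  estimates when the quadratic is not concave); the richness estimate is
  the Gaussian area $h\,w\sqrt{2\pi}$, clamped below at $S_{obs}$. At least
  3 occupied octaves are required; fewer is a fit-degeneracy error.
* **ACE**: rare/abundant cutoff at total abundance 10 (the standard
  convention, configurable); zero coverage (all rare species singletons)
  falls back to Chao1 with a warning.
* **Degenerate inputs**: empty record sets, single-site CNE/Chao2 input,
  incidence input to abundance-based estimators, and unassigned sites in
  grouped analyses are explicit errors; inapplicable estimators inside
  `benchmarkEstimators()` yield NA rows rather than failures.

## Limitations

* No variance or confidence intervals for the point estimators (the CNE and
  Chapman estimators are reported as point values only).
* The sampling-intensity-corrected estimator family is supported only as a
  plug-in hook (`estimateRichness(extra = ...)`); their correction formulas
  are not implemented here.
* The CNE's bias advantage at low coverage comes with visibly higher
  variance, and single extreme sites can dominate $\hat Q_1$; the per-site
  breakdown returned by `cneEstimate()` should be inspected when estimates
  look surprising.
* Species identity is the exact taxon label; no reconciliation against
  taxonomic databases is attempted.
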