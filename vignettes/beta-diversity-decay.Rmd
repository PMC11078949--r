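---
title: "Partitioned beta-diversity decay over space, season and latitude"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned beta-diversity decay over space, season and latitude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the data structure

Repeated weekly harvests of flight-intercept (Malaise) traps at
georeferenced sites produce one community sample — a *trapping event* —
per site and week: a set of species identifiers detected at that site in
that week. Comparing all pairs of trapping events asks how community
composition turns over along three axes at once: distance in space,
distance in season, and position along the latitudinal diversity
gradient (LDG). `betadecay` implements that comparison as a reusable,
tested pipeline: dissimilarity partitioning, pairwise covariates,
balanced weighted regression, and permutation inference.

Abundances are deliberately discarded: all analyses run on
presence/absence, because detection intensity in mass trapping varies
with effort and season in ways that composition does not.

## Partitioning pairwise dissimilarity

For two communities, let $a$ be the number of shared species and $b$,
$c$ the numbers unique to each side. Total dissimilarity is Jaccard,

$$\beta_{tot} = \frac{b + c}{a + b + c},$$

and the Podani-family decomposition splits it into *species
replacement* (one-for-one substitution) and *richness difference* (one
community simply holding more):

$$\beta_{repl} = \frac{2\min(b, c)}{a + b + c}, \qquad
  \beta_{rich} = \frac{|b - c|}{a + b + c}, \qquad
  \beta_{repl} + \beta_{rich} = \beta_{tot}.$$

Because each pair's components are exact integer ratios computed from
$(a, b, c)$, the conservation identity holds to machine precision, which
the test suite asserts on random data. `partition_pairs()` obtains all
$n(n-1)/2$ triples at once from one cross-product of the binary
incidence matrix and stores the three components as condensed
lower-triangle vectors in a documented row-major $(i < j)$ order — at
thousands of events, full square matrices would waste memory for no
benefit.

Pairs of *empty* communities have an undefined denominator; empty events
are therefore dropped (and reported) at load time rather than carried as
all-zero rows.

## Pairwise covariates

Three covariates describe each unordered pair of trapping events:

* **Distance in space** ($\Delta S$): great-circle (haversine) distance
  between the two sites in meters, on a sphere of radius 6,378,137 m
  (delegated to `geosphere::distHaversine()`, whose default radius this
  is). Pairs of events from the same site have $\Delta S = 0$ and are
  kept by default: repeat sampling at one site is precisely what
  identifies the temporal terms.
* **Distance in season** ($\Delta T$): day-of-year differences are
  angles on the annual circle at 0.986°/day, folded to the shorter arc,
  $\min(\theta, 360 - \theta) \in [0, 180]$ degrees. December 31 and
  January 1 are one day apart, not 364. Converting days to degrees by
  *multiplication* with 0.986 is the only direction of the conversion
  that keeps the second arc nonnegative (a 365-day difference divided by
  0.986 would exceed 360°); as a linear rescaling of the covariate it
  has no effect on permutation p-values or coefficient signs.
* **Mean absolute latitude** (Lat): $(|lat_1| + |lat_2|)/2$, the pair's
  position along the LDG. A pair at the Equator scores 0°, a pair at the
  two Poles 90°, a Pole-Equator pair 45°.

Year identity is intentionally discarded: two events on the same day of
year in different years have $\Delta T = 0$, consistent with the
circular metric's purpose of measuring *seasonal* separation.

## Balanced weights

Sites are sampled for different numbers of weeks, so an unweighted
regression over event pairs would let heavily sampled site pairs
dominate. If $n_{s_1 s_2}$ event pairs join sites $s_1$ and $s_2$, every
such pair receives weight $1/n_{s_1 s_2}$, making each site pair's total
weight exactly 1 (within-site "pairs" $s, s$ count $\binom{k}{2}$ event
pairs). The tests verify both the per-site-pair normalisation and the
equivalent invariance: duplicating rows at half weight leaves the fitted
coefficients unchanged.

## The model and its likelihood

Each component is modelled, on its original $[0,1]$ scale, as a linear
function of $\Delta S$, $\Delta T$, Lat and the interactions
Lat×$\Delta S$ and Lat×$\Delta T$; the interactions ask whether the
*rate* of spatial or seasonal decay itself changes along the LDG.
`fit_wls()` solves the weighted least-squares problem by QR — no
iterative optimisation, so fits are deterministic. The Gaussian
log-likelihood treats weights as error precisions,

$$\hat\sigma^2 = \tfrac{1}{n}\textstyle\sum_i w_i r_i^2, \qquad
  \ell = \tfrac{1}{2}\left[\sum_i \log w_i - n(\log 2\pi\hat\sigma^2 + 1)\right],$$

matching `stats::logLik()` on an equivalent `lm(weights = )` fit (the
suite asserts this identity). The weight-dependent constant
$\sum \log w_i$ cancels in every log-likelihood ratio between models
fitted to the same pair table, so its inclusion is inert for inference.

## Permutation inference

Event pairs are not independent — every event takes part in $n - 1$
pairs — so parametric tests on the pair-level regression would be
anti-conservative. Instead, each term is tested by comparing the
observed log-likelihood ratio (LLR) between a full model containing the
term and a reduced model without it against its distribution under
permutations of the *exchangeable units*:

| term | full model | scheme |
|---|---|---|
| Lat×ΔS | all five terms | permute site attributes |
| Lat×ΔT | all five terms | permute site attributes, then dates within sites |
| ΔS | drops Lat×ΔS | permute site attributes |
| Lat | drops both interactions | permute site attributes |
| ΔT | drops Lat×ΔT | permute dates within sites |

Main effects are tested in full models that exclude the interaction(s)
associated with the tested variable, so the LLR isolates the main
effect. For the latitude main effect both latitude interactions are
excluded: both are "associated with" latitude, and excluding only one
would make the test depend on an arbitrary ordering.

Permuting "site attributes" reassigns the (latitude, longitude) tuples
across sites while every site keeps its own events: communities, dates
and therefore all three response vectors are untouched, and the
condensed partitions are computed once and reused across all tests and
permutations — a major optimisation that is exact, not approximate.
Region labels stay with the physical site group; within a regional scope
this is vacuous, and in the global scope region labels never enter the
model. Date permutation reshuffles each site's observed multiset of
days among that site's events.

The p-value is the proportion of permutations whose LLR *strictly*
exceeds the observed one, which permits exact 0 and 1; a conservative
$(b+1)/(N+1)$ variant is available via `tie_rule = "conservative"`. The
reported direction is the sign of the focal coefficient in the full
model on the observed data. With $N = 199$ permutations and
$\alpha = 0.05$ the strict rule is exactly calibrated
($P(p \le 0.05) = 10/200$) under exchangeability, which is what the
calibration suite measures. Rank-deficient permuted designs are redrawn
(with a hard cap); a rank-deficient *observed* design is an error
identifying the collinear term.

`run_full_analysis()` assembles the full grid — five terms × scopes
(global plus each region) × three components — with one child seed per
cell derived deterministically from the master seed, so any cell can be
reproduced in isolation. Scopes with fewer than 3 sites or 30 pairs are
skipped with a warning (both floors configurable). No multiplicity
correction is applied across cells; cells are reported as a table of
per-test p-values.

## The simulator

`simulate_metacommunity()` exists so that calibration and power claims
about the pipeline are *measured*, not asserted. It emulates the
structure of a multi-region weekly trapping campaign:

* **Sites**: 5 regions with continental latitude/longitude bands; sites
  latitude-stratified within each band (marginally uniform, but every
  realisation spans the band, as a designed trap network would).
* **Latitudinal structure**: species latitudinal range limits
  $L \sim \mathrm{Exp}(\texttt{lat\_diversity\_slope})$; a species
  occupies $|lat| \le L$. The local pool at absolute latitude $x$ then
  has expected size $G e^{-\texttt{slope}\, x}$ — the slope is literally
  the relative decline in pool size per degree — and species reaching
  high latitudes necessarily have wide, mutually nested ranges, so
  high-latitude communities overlap strongly while equatorial
  communities are drawn from a large pool and overlap little. At slope
  0 every range is unbounded and latitude has no effect at all.
* **Spatial structure**: each species has a geographic range centre;
  suitability decays as $e^{-\texttt{distance\_decay\_rate} \cdot d}$
  (per km). Each site draws a fixed-size community without replacement
  with these suitabilities as weights.
* **Richness-difference structure**: a `replacement_vs_nestedness_mix`
  fraction of the community is assembled as above (generating
  replacement); the rest comes from a commonness-ranked pool truncated
  per site, producing strictly nested communities (generating richness
  difference). At the extremes the suite verifies the corresponding
  component is exactly zero.
* **Season**: each species has a circular-Gaussian activity window
  (s.d. `seasonal_niche_breadth` degrees, peak uniform on the circle);
  weekly events detect locally present, currently active species
  independently with `detection_prob`.

Two presets freeze the study conditions used by the test suites.
`null_preset()` (5 regions × 2 sites, 8 weeks, 200 species, community
40, detection 0.85, no latitudinal/spatial/seasonal structure, pure
replacement) makes site attributes and dates exchangeable by
construction; on 100 such campaigns the rejection rate of every term's
test is required to sit inside the exact binomial 95% band around 0.05.
`effect_preset()` (5 regions × 5 sites, 14 weeks, pool 400, community
50, slope 0.03/deg, decay 2e-4/km, seasonal s.d. 45°, detection 0.8,
mix 0.9) builds in strong monotone structure; on 20 such campaigns the
global Latitude (−), ΔS (+) and ΔT (+) tests on total dissimilarity are
required to reject in at least 90% of replicates.

The preset scales were chosen to exercise the identical code paths as a
full campaign at desk scale; the calibration result is exact at any
size, while power naturally grows with site count. Two design findings
are worth recording. First, the number of *sites* — not weeks — limits
the site-permutation tests, because sites are their exchangeable units.
Second, pushing the latitudinal slope too high is counterproductive:
once the high-latitude pool falls below the community quota, communities
are topped up with effectively random "vagrants", and that noise erodes
the very gradient the slope was meant to strengthen. The preset sits
near the point where the polar pool matches the quota.

What the simulator does *not* emulate: abundance structure (the pipeline
is presence/absence only), taxonomic structure, habitat covariates,
elevation, multi-year trends, spatially autocorrelated detection, or
hemisphere-shifted seasons (activity windows follow absolute day of
year). Passing calibration and recovery on these synthetic campaigns
demonstrates the statistical machinery is correct and sensitive under
the stated structure; it does not certify field-data effect sizes.

## Numerical and design notes

* Pair enumeration order (row-major $i < j$) is part of the public
  contract of every condensed structure and of the pair-table CSV.
* Components are computed per pair from integer $(a,b,c)$; no streaming
  accumulation, so no floating-point drift across pairs.
* A fitted residual variance below $10^{-12}$ is treated as a degenerate
  likelihood and refused, rather than returning an effectively infinite
  log-likelihood.
* Distances are kept in meters internally; the regression is
  scale-equivariant, so units only rescale coefficients, never
  p-values or signs.
* The global scope includes cross-region and within-site pairs by
  default; both are documented toggles of `build_pair_table()`
  (`include_cross_region`, `include_within_site`), since a "global"
  analysis restricted to within-region pairs would be a mere union of
  the regional analyses.
* Duplicating every observation at half weight halves $\hat\sigma^2$
  under the $\sum w_i r_i^2 / n$ convention while leaving coefficients
  and site-pair influence unchanged; the suite pins down the coefficient
  invariance, which is the property the balancing weights rely on.
* Simulator phases (site placement, species traits, community assembly,
  detections) run on separately derived substreams of the master seed,
  so e.g. adding weeks does not move the sites.

## Problem sizes used by the shipped analyses

The numbered scripts under `analysis/` and the test suites run, by
design, at desk scale: the pair-count identity is exercised on a
simulated 2412-event campaign (2,907,666 pairs), calibration on 100
null campaigns of 80 events (3,160 pairs) at $N = 199$ permutations,
and recovery on 20 effect campaigns of 350 events (61,075 pairs) at
$N = 199$. A publication-grade run would raise $N$ to 1000 per cell —
`n_perm` is a single argument everywhere.
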