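---
title: "Generating and calibrating commuting origin-destination networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and calibrating commuting origin-destination networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commod)
```

## The problem

Metapopulation models of epidemic spread, traffic planning and regional
economics all need the full origin-destination (OD) matrix of commuting:
how many people live in geographic unit $i$ and work in unit $j$. Census
offices rarely publish that matrix, but they routinely publish its
*margins* -- for every unit, the number of resident commuters
($s_i^{\mathrm{out}}$) and the number of jobs filled by in-commuters
($s_j^{\mathrm{in}}$). `commod` reconstructs the full matrix from those
margins with a single-parameter stochastic model, provides the statistic
used to calibrate that parameter, a scaling law that predicts the
parameter when no flow data exist at all, and the comparator models
(radiation, margin-based radiation, uniform random) against which the
approach is usually judged.

## The allocation model

Commuters are placed one at a time. Each step:

1. pick an origin $i$ uniformly at random among units with remaining
   out-commuters $s_i^{\mathrm{out}}(t) > 0$;
2. draw its workplace $j$ with probability
   $$P_{i \to j} \;\propto\; s_j^{\mathrm{in}}(t)\, e^{-\beta d_{ij}},$$
   where $d_{ij}$ is the Euclidean distance between unit centroids in
   meters and $s_j^{\mathrm{in}}(t)$ the remaining in-capacity of $j$;
3. record the trip and decrement both margins.

The loop ends when every commuter is placed. Because capacity is
decremented, a complete run reproduces the out-margins exactly and never
exceeds the in-margins: the result is a doubly-constrained network
without any matrix-balancing step, and the margins need not sum to the
same total (in-capacity only has to suffice). The single parameter
$\beta$ (units m$^{-1}$) sets how strongly distance deters the choice:
at $\beta = 0$ the choice is distance-blind and the allocation law is
exactly multivariate hypergeometric (a property the test suite checks
against the closed-form distribution); at large $\beta$ all probability
concentrates on the nearest eligible destinations.

Two readings of "pick an origin at random" are offered:
uniform over units with remaining commuters (the default) and
proportional to remaining out-commuters (`origin_selection =
"by_remaining"`, i.e. uniform over unplaced individuals). They differ
only in allocation order; complete runs have identical margins either
way.

**Self-loops.** Census commuter margins count people working outside
their residence unit, and $d_{ii} = 0$ would otherwise make the
diagonal dominate the choice, so flows $i \to i$ are excluded by
default (`self_loop_policy = "include"` reverses this). A consequence
is that an origin can *starve*: all remaining capacity may sit on the
origin itself. Since capacity only shrinks, starvation is permanent,
so the generator retires such origins and returns a partial matrix
flagged `complete = FALSE` with the count of unplaced commuters,
rather than raising an error.

**The extended area.** Units carry a role: `core` units are origins
and destinations; `extended` units, a ring around the study region,
are destinations only. They absorb out-of-region commuting and reduce
border effects; they are excluded from the average-surface descriptor
below because they are a correction device, not part of the studied
region (`average_surface(include_extended = TRUE)` reverses that
choice).

**Implementation.** The hot loop is compiled (Rcpp) and draws from R's
RNG, so a fixed `(case, beta, seed)` gives a bit-identical matrix, and
the pure-R reference allocator in the test suite reproduces it
draw-for-draw. Only the drawn origin's weight row is recomputed at each
step -- after one allocation only one destination's capacity changed,
so a full-matrix recompute is never needed; recomputing the single row
rather than caching and decrementing it keeps the arithmetic exact
(cached rows drift under millions of repeated subtractions). A
1,000-unit, $10^6$-commuter run costs $10^6$ row scans of length
1,000, well under a minute.

## Goodness of fit: the common part of commuters

Calibration maximizes the common part of commuters (CPC), a
Sørensen-type similarity between the observed matrix $T^{obs}$ and a
simulated one $T^{sim}$:
$$\mathrm{CPC} = \frac{2 \sum_{ij} \min(T^{obs}_{ij}, T^{sim}_{ij})}
                      {N^{obs} + N^{sim}},$$
with $N$ each matrix's total flow. CPC is 1 exactly for identical
matrices and 0 when the supports share no mass; when
$N^{obs} = N^{sim}$ (always true for complete runs of this model) it is
literally the fraction of commuters placed on the correct
origin-destination pair. MAE and RMSE (means over all cells of the
compared index set) and NMAE are provided as companions. NMAE has no
single standard definition; here it is
$\sum_{ij} |T^{sim}_{ij} - T^{obs}_{ij}| / N^{obs}$, chosen because it
is scale-free and, like CPC, referred to the total observed flow.

## Calibrating the distance-decay parameter

`calibrate_beta()` is a grid search: 25 log-spaced points over
$[10^{-6}, 10^{-2}]$ m$^{-1}$, then one refinement pass of 11
log-spaced points spanning the two coarse neighbours of the coarse
argmax. At every $\beta$ the network is regenerated `replications`
times (default 10) with seeds `seed + 0, ..., seed + R - 1` -- the
*same* seeds at every grid point, so grid comparisons use common random
numbers and the whole trace is reproducible. $\beta^\*$ is the argmax
of mean CPC over all evaluated points, smallest $\beta$ on ties.
A grid (rather than a derivative-based optimizer) is deliberate: the
replicated CPC is a stochastic, piecewise-flat objective, and the grid
makes the tie-break and reproducibility contracts exact.

## The surface law

Across case studies, the calibrated $\beta$ follows a power law in the
average surface $\bar S$ (km², core units, non-dimensionalized by
1 km²) of the geographic units:
$$\beta = \alpha \, \bar S^{-\nu}.$$
`fit_universal_law()` fits it by OLS in the log-log plane
($\alpha = e^{\mathrm{intercept}}$, $\nu = -\mathrm{slope}$), and
`predict_beta()` evaluates it, so an OD matrix can be generated for a
region where no flow data exist. The published constants
($\alpha = 3.15 \times 10^{-4}$ m$^{-1}$, $\nu = 0.177$, fitted on 80
census case studies) ship as a flat config file
(`inst/extdata/universal_law.conf`, read by `read_law_constants()`);
they are data, not logic -- every law computation in the package is
exercised against planted synthetic laws.

`cross_validate()` reproduces the robustness check used for that law:
repeatedly split the case collection into a training and a test set,
fit the law on the training calibrations, predict $\beta$ for each test
case from its average surface alone, and compare the CPC at the
predicted $\beta$ with the CPC at the case's own calibrated $\beta$.
Each case keeps a fixed evaluation seed across repeats so the two CPCs
are directly comparable; all split assignments are drawn up front from
the master seed so evaluation randomness cannot perturb the splits.

## Comparator models

The radiation model is the standard parameter-free benchmark:
$$T_{ij} = T_i \frac{m_i n_j}{(m_i + s_{ij})(m_i + n_j + s_{ij})},
  \qquad T_i = m_i \frac{N_c}{N},$$
with $m_i, n_j$ unit populations, $N$ total population, $N_c$ total
commuters and $s_{ij}$ the population strictly inside the circle of
radius $d_{ij}$ centred at $i$, excluding source and destination. The
margin-based variant replaces the emission $T_i$ by the observed
out-commuters $O_i$ and every mass by in-commuter counts, so it
consumes exactly the same inputs as the allocation model. Numerical
choices: circle membership is strict ($d_{ik} < d_{ij}$; a unit exactly
at the radius is on the ring, not inside), with an optional `tol` to
absorb floating-point ties; the analytical approximation is used as
published, i.e. row sums are *not* rescaled to $T_i$ (a finite-size
property) unless `normalize_rows = TRUE`; outputs stay real-valued for
metric comparison, with `stochastic_round()` available for integer
export. A uniform-random baseline (`generate_random_network()`) runs
the same allocation loop with uniform destination probabilities over
eligible destinations, capacity still decremented, so it isolates the
contribution of the distance-decay weights.

## The synthetic case-study generator

Everything above is testable without census downloads because
`synth_case_study()` builds self-contained case studies with the
statistical structure the model assumes: core centroids uniform in a
square of side `extent_km`; extended centroids on a surrounding ring at
0.75-1.0 extents from the centre (fully outside the square); surfaces
equal to `extent_km^2 / n_core` jittered ±20%; heavy-tailed lognormal
populations (median 2,000, log-sd 1 by default, emulating the
municipality-to-county range); out-commuters a fixed fraction (default
0.1) of core populations, giving roughly 10,000 commuters on the
default 30-core-unit configuration; and ground-truth flows produced by
the allocation model itself at a known `beta_true` (default
$2 \times 10^{-4}$ m$^{-1}$, so that trips across the default 100 km
region span the sensitive range of the decay).

Two design points deserve emphasis:

* **Margins are back-filled.** After the ground truth is drawn, each
  unit's margins are replaced by the realized row/column sums, so the
  case study is exactly self-consistent -- its margins are the
  marginals of its (normally unobserved) true matrix, precisely as
  census margins are -- and calibration has an exactly feasible target.
* **Provisional capacity carries a surplus.** Before the ground truth
  exists, in-capacity is assigned proportionally to population but
  scaled to `(1 + capacity_surplus)` times total demand (default 1.2x)
  and capped per unit at feasibility ($s_i^{\mathrm{in}} \le
  \sum s^{\mathrm{out}} - s_i^{\mathrm{out}}$). With exactly balanced
  provisional margins and self-loops excluded, a unit holding a large
  share of *both* margins starves systematically (its own commuters are
  the only demand left for its own jobs); a modest surplus -- the role
  the extended area plays for real regions, where jobs always exceed
  any one realization of filled positions -- removes the degeneracy.
  The back-filled final margins still balance exactly. If a draw
  starves anyway, the whole case (not just the allocation) is redrawn
  from the next seed, up to five times.

`synth_law_suite()` builds a collection of such cases whose
ground-truth betas lie exactly on a planted power law, by log-spacing
the target surfaces and setting `extent_km` so the units tile each
surface; it is the harness behind the law-recovery and
cross-validation-coherence tests.

What the generator does *not* emulate: real geographies (coastlines,
road networks, anisotropic settlement), spatially correlated population
density, job-market structure, or reporting noise in census margins.
Passing tests therefore demonstrate that the implementation is faithful
to the model and that the calibration/law machinery recovers planted
truth under the model's own assumptions -- not that the model fits any
particular real region.

## Problem sizes and numerical choices in the test suite

The shipped tests run the default synthetic scale: 30 core + 8 extended
units and roughly 10,000 commuters per case; the planted-law recovery
suite uses 10 such cases with betas spanning
$[5 \times 10^{-5}, 10^{-3}]$ m$^{-1}$ (surfaces 1-400 km²), 10
replications per grid point; cross-validation coherence uses 6 smaller
cases. The $\beta = 0$ distributional check compares 20,000 seeded runs
of a 1-origin/2-destination case against the closed-form multivariate
hypergeometric law by chi-square at the 1% level. The whole suite
completes in well under a minute on one CPU.

One behavioural subtlety: mean commute distance decreases with $\beta$
only while destination capacity is not strongly binding. Under tight
margins a very large $\beta$ makes early commuters saturate nearby
capacity greedily, forcing late commuters far away, which can lengthen
the mean trip again; the monotonicity test therefore runs on a case
with ample capacity, where the effect the property describes is not
confounded by packing.

## Limitations

* Distances are Euclidean between centroids, in planar (projected)
  meter coordinates; longitude/latitude input is rejected rather than
  silently projected, and road-network or geodesic distances are out of
  scope.
* Only the exponential deterrence function is implemented.
* The starvation rule returns flagged partial matrices; downstream
  statistics on incomplete runs are computed on the placed flows.
* The shipped law constants come from census calibrations at
  municipality-to-county scales in western industrialised countries;
  nothing here validates them elsewhere.
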