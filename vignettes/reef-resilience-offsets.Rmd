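---
title: "Metapopulation resilience and conservation offsets on reef dispersal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metapopulation resilience and conservation offsets on reef dispersal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

`reefresilience` simulates a metapopulation of `n` reef sub-populations
(nominally the 114 reefs of a long fringing-reef system such as Ningaloo,
Western Australia, and a site-attached fish like the spangled emperor).
Each sub-population carries a biomass $X_i$ scaled to its carrying capacity
and obeys coupled logistic–migration dynamics:

$$\frac{dX_i}{dt} = r X_i (1 - X_i) \;-\; s\,r\,X_i\,\phi_i \;+\; I_i(X),$$

where $r$ is the per-unit-time growth rate (default 0.2, a value reported
for a congeneric emperor species), $s \in [0,1]$ is the *connection
quality* — the survivorship of migrating recruits — and $I_i$ is
immigration. Migration moves the productive component of the population
(recruits), not settled adults, so the exported flux is proportional to
$rX_i$.

Connectivity is distance-based. Each ordered pair at Euclidean distance
$D_{ij}$ (model spatial units) receives the base weight

$$w_{ij} = e^{-3.4\,D_{ij} - 3.91},$$

and only pairs with $w_{ij} > 0.01$ (strict) are kept as directed links.
The decay constants come from hydrodynamic dispersal fits for reef systems
and are treated as given; the threshold implies a maximum link distance of
$(\ln 100 - 3.91)/3.4 \approx 0.2045$ units. On the reference 114-node
layout this rule yields 3904 directed links (1952 reciprocal pairs — links
are stored and counted as ordered pairs because the dynamics route flow
directionally). Self-links are excluded: although $w_{ii} = e^{-3.91} > 0.01$,
migration from a reef to itself is meaningless here. *Connection quantity*
$\alpha$ is varied by retaining a uniformly random subset of the directed
links.

### The immigration closure

A flux-balance reading of the model — emigrants leave with $s r X_j$ and
land somewhere — does not pin down how the pooled flux is distributed, and
the natural per-pair form $k_i \tilde X$ with
$k_i = \sum_j L_{ji} X_j / \sum_j L_{ji}$ and $\tilde X = r \sum_j X_j$ is
not mass-conserving: on any connected network with $s > 0$ total
immigration exceeds total emigration by roughly a factor $n$, and the
system diverges (this is demonstrable in closed form on three equidistant
reefs, and `migration_mode = "literal"` reproduces it). The package
therefore offers three closures and defaults to the conservative one:

* **conservative** (default): source $j$ emits
  $s r X_j \cdot W^{sel}_j / W^{full}_j$, where $W^{sel}_j$ and
  $W^{full}_j$ are the selected and full-network out-weight totals, and the
  flux is split over its selected out-links proportionally to their base
  weights. Removing a dispersal corridor removes the flow that used it —
  it is not re-routed — so total immigration equals total emigration at
  every instant (tested to $10^{-10}$).
* **pool**: all emigrant flux enters a common pool allocated to
  destinations in proportion to their weighted in-flow
  $\sum_j w_{ji} X_j$; also conserving, but allocation is global.
* **literal**: the divergent per-pair form above, retained for
  demonstration; the integrator aborts with an informative error when the
  state leaves the finite range.

Why the corridor-scaled emigration? Without the $W^{sel}/W^{full}$ factor a
node would keep exporting its entire $s r X_j$ through however few links
survive subsampling. A node that draws out-links but no in-links then
obeys $\dot X = rX(1 - s - X)$: its equilibrium collapses to $1-s$ and its
post-disturbance regrowth rate to $r(1-s)$, so as $s \to 1$ heavily
subsampled networks fill with drained, arbitrarily slow patches — recovery
time *increasing* in connection quality, the opposite of the monotone
quality/quantity trade-off this model exists to study, and an artefact of
treating the lumped emigration term as independent of the link set.
Reading the connectivity matrix as per-pair migration fractions removes
the artefact (the property tests assert the monotone response on a
6 × 5 sweep at 1000 replicates per cell) and leaves the full-network
dynamics — and every scenario result on the full 3904-link set —
bit-for-bit unchanged.

## Disturbance experiments

A disturbance event removes 99% (configurable) of the biomass of every
sub-population within 0.4 model units of a centre drawn uniformly on the
bounding box of the reef coordinates (boundary inclusive). By default
centres that hit no reef are redrawn (`require_hit = TRUE`): the
published dispersion of recovery times is inconsistent with a point mass
of zero-length recoveries, and a "disturbance" that touches nothing is not
an event in this design. The flag is switchable, and the miss rate with it
off matches the geometric coverage fraction of the dilated node set
(tested against a rejection-sampling oracle).

Each replicate runs the pipeline: draw an $\alpha$-subset of links → relax
the undisturbed system to equilibrium → draw an event → remove biomass →
integrate until the **aggregate biomass of the entire metapopulation**
(disturbed and undisturbed reefs alike) first reaches 95% of its
pre-disturbance value at a unit-time checkpoint. That checkpoint index is
the recovery time (Pimm resilience); replicates that exhaust the horizon
(500 units) are censored and excluded from cell means, which the surface
object counts separately. "Time steps" are unit model-time intervals, not
integrator steps — forced by the exact $1/r$ scaling of the isolated-reef
recovery times (45.2/33.9 = 4/3 for $r$ 0.15 vs 0.2).

The pre-disturbance baseline is the **relaxed equilibrium**, not the
all-ones state: with migration active the all-ones state is not
stationary, and "recover 95% of the initial state" presupposes a
stationary initial state. For $s = 0$ the two coincide.

### Numerical choices

* Classical fixed-step RK4 with `dt = 0.05` (the step divides the unit
  checkpoint interval exactly); against the logistic closed form the
  checkpoint error is below $10^{-6}$ and shrinks ~16× per step halving.
* Biomass is clipped at 0 after every step; with these dynamics the clip
  is a safety net rather than an active constraint.
* Burn-in relaxation integrates from all-ones until
  $\max_i |dX_i/dt| < 10^{-9}$, using its own step `relax_dt = 0.25`:
  fixed points of the RK4 map coincide with those of the ODE, so a coarser
  burn-in step changes only the approach path. Non-convergence within the
  horizon is an error that reports the residual.
* Replicate seeds derive hierarchically from `(base_seed, cell,
  replicate)`, so any grid cell is reproducible in isolation, and the
  link-sampling and event-placement draws use separate streams — at
  $s = 0$ a replicate's recovery time is therefore *exactly* invariant to
  $\alpha$, a property the tests assert replicate-by-replicate.

## The synthetic reef strip

The package ships no coordinates; `synthesize_reef_nodes()` generates the
study network. It emulates an elongated fringing-reef strip: a 15:1
rectangle (a ~300 km reef tract is roughly 1.45 model units long at these
kernel constants), with reefs clustered around hard-core-spaced parent
points (patchy habitat) and, by default, the realized layout rescaled by
bisection until the link rule delivers the reference density of
3904/114 ≈ 34.25 directed links per node. Two published statistics pin the
remaining geometry *a priori*, with no dynamics in the loop:

* the link count / degree target above, and
* the isolated-system mean recovery time (33.9 steps at $r = 0.2$), which
  through the logistic closed form fixes the mean fraction of biomass a
  0.4-radius event removes at about 0.45 of the strip.

The clustered layout then reproduces the published replicate dispersions
(about ±2.4 recovery-time steps at $s = 0$ and ±3.3 at $s = 1$; the
acceptance script reports the simulated values) without being tuned to
them — patchiness, not the mean geometry, generates that variance. What the
stand-in does **not** capture is the true reef layout: curvature of the
coast, gaps, and the exact adjacency structure. Scenario means that depend
only weakly on layout (isolated reefs; uniform migration; shallow
disturbance) reproduce the published values closely, while
spatially-localized rescue (the connected base case) is geometry-sensitive
at the level of ±2 time steps — a uniform unclustered strip shifts it by
about two steps on its own. Passing tests therefore validate the
dynamics, the experiment machinery and the trade-off structure, not the
exact recovery time of the real Ningaloo layout.

Scenario overrides follow the sensitivity design: "no spatial effect"
connects **every** ordered pair with weight 1 (there must be no penalty
for migration between the strip's extremes, which rules out merely
re-weighting the 3904 retained links); "twice spatial effect" doubles the
decay slope to 6.8 and re-applies the 0.01 threshold, halving the link
radius. Latitude-gradient scenarios use $r_i = 0.2 + g (y_i - \bar y)$
with $g$ scaled so $\max_i |r_i - 0.2| = 0.05$: the printed form of the
gradient has the units of the coordinate file baked in and yields absurd
or negative rates for any plausible span, so the magnitude is an explicit
parameter and these scenarios are reported qualitatively only.

## The iso-resilience / offset layer

`run_grid()` sweeps 11 quality levels × 10 link counts (the published
design; replicate count configurable — the full 10 000-replicate sweep is
hours of CPU, and 150–1000 replicates per cell already give standard
errors well below the structure in the surface). `fit_surface()`
interpolates cell means bilinearly; optional isotone smoothing (alternating
row/column pool-adjacent-violators passes) restores the monotone
non-increase in both axes that Monte-Carlo noise obscures — the published
smooth contours imply some such regularization without describing one.
`iso_contour()` extracts marching-squares contours: the planner's
indifference curves between connection quality and quantity.

Budgets are linear: cost $c_s s + c_\alpha \alpha \le B$, with the axis
intercepts giving the total budget in each pure investment.
`optimize_under_budget()` finds the best attainable recovery time under a
budget (dense grid search plus local refinement; on a strictly decreasing
surface the optimum sits on the budget frontier — the tangency of the
budget line with the outermost reachable iso-resilience curve).
`min_budget_for_target()` solves the offset problem: after a permanent cap
on the number of connections, the cheapest $(s, \alpha)$ restoring a
target recovery time, found by bisection in $s$ (valid on the monotone
smoothed surface) inside a sweep over $\alpha$. The published illustration
— restoring a recovery time of 28.5 with connections capped at 800 by
raising quality from 0.12 to about 0.62 — used unprinted cost
coefficients and a hand-drawn budget line, so it is a qualitative anchor:
the simulated surface reproduces the direction and rough magnitude of the
required quality increase, and the acceptance script recomputes the
$s$ required at the cap each run. $\alpha$ is treated as continuous in the
optimizers and rounded only in reported solutions (grid spacing is
hundreds of links).

## Problem sizes used in the checks

The test suite runs the scenario columns at 2000 replicates ($s = 0$) and
500 replicates ($s = 1$) per scenario, pooled over several independent
strips so that the stand-in geometry's between-strip variance is part of
the reported uncertainty; the property sweep uses a reduced 6 × 5 grid at
1000 replicates per cell; the acceptance script runs the full 11 × 10 grid
at 150 replicates per cell. These sizes were chosen so every statistic's
Monte-Carlo standard error is small against the tolerances being checked.

## Known limitations

* The real reef coordinates are not distributed here; all quantitative
  results are for the calibrated synthetic strip, with the geometry
  sensitivity noted above.
* The published immigration term is not integrable as printed; the
  conservative closure is this package's choice, and the two conserving
  closures bracket the plausible readings.
* No demographic or environmental stochasticity, age structure, or
  harvest; disturbances are instantaneous, uncorrelated and spatially
  uniform.
* Budget constraints are linear only; nonlinear cost structures and
  multi-species offsets are out of scope.
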