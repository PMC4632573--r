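# reefresilience

Recovery-time (Pimm) resilience of a reef-fish metapopulation on a
distance-decay dispersal network, and the conservation-offset arithmetic it
supports. The package is built around a question faced by marine
conservation agencies: when human activity permanently removes migration
corridors between reef sub-populations, how much must be invested in the
*quality* of the remaining connections to keep the system recovering from
disturbances as fast as before — and what is the cheapest such offset?

## The model

`n` reef sub-populations (nominally the 114 reefs of a ~300 km fringing
reef tract) carry biomass `X_i` scaled to carrying capacity and follow
coupled logistic–migration dynamics

    dX_i/dt = r X_i (1 - X_i) - s r X_i φ_i + I_i(X)

where `r` is the growth rate (0.2 by default), `s ∈ [0, 1]` is connection
quality (migrant survivorship), `φ_i` the retained fraction of node `i`'s
dispersal corridors, and `I_i` immigration routed along the directed link
set built from the dispersal kernel `exp(-3.4 D - 3.91)` thresholded at
0.01 (3904 directed links on the reference layout). Connection quantity
`α` is varied by uniform subsampling of links. Monte-Carlo disturbance
experiments remove 99% of biomass within 0.4 units of a random point and
measure the number of unit time steps until aggregate biomass regains 95%
of its pre-disturbance equilibrium. Sweeping `(s, α)` yields an
iso-resilience surface; marching-squares contours of that surface are the
planner's indifference curves, and linear-budget optimizers compute
best-attainable resilience under a budget and the minimum budget restoring
a target resilience under a connection cap.

See the methods vignette (`vignettes/reef-resilience-offsets.Rmd`) for the
migration closures, the calibration of the synthetic reef strip, and all
numerical choices.

## Worked example

```r
library(reefresilience)

nodes <- synthesize_reef_nodes(seed = 1)   # calibrated 114-reef strip
links <- build_links(nodes)
links
#> reef_links: 3902 directed links on 114 nodes (mean out-degree 34.2)
#>   kernel exp(-3.4 d - 3.91), threshold 0.01 (cutoff distance 0.2045)

# one seeded disturbance-recovery replicate at full connectivity
run_replicate(nodes, links, model_params(s = 1), seed = 7)
#> recovery_result: 27 time steps (disturbed 78 nodes, aggregate 113.4 -> 34.8)

# the same disturbance with reefs isolated recovers more slowly
run_replicate(nodes, links, model_params(s = 0), seed = 7)
#> recovery_result: 36 time steps (disturbed 78 nodes, aggregate 114 -> 36.78)

# a small quality-by-quantity sweep and the offset question
surf <- run_grid(nodes, links, s_values = seq(0, 1, 0.25),
                 alpha_values = c(200, 1100, 2000, 3000, nrow(links)),
                 n_reps = 100, base_seed = 1)
model <- fit_surface(surf, smooth = TRUE)
min_budget_for_target(model, target = 32, alpha_cap = 2000,
                      budget_model(c_s = 1000, c_alpha = 1))
#> offset_solution: s = 0.7511, alpha = 1667 -> recovery time 32.000
#>   budget required 2418 (binding: target)
```

The first replicate reads: the event disturbed 78 of 114 reefs, cutting
aggregate biomass from 113.4 to 34.8 (in carrying-capacity units), and the
connected metapopulation regained 95% of its equilibrium biomass after 27
unit time steps — nine steps faster than the same reefs with migration
switched off. The offset solution reads: with connections capped at 2000,
the cheapest way to hold mean recovery time at 32 steps under these unit
costs is quality ≈ 0.75 with 1667 connections, at a budget of
`0.751·c_s + 1667·c_α ≈ 2418`.

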