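# hemigait

Simulation and analysis of a bilateral spinal locomotor circuit before and
after a lateral thoracic hemisection.

## What this package is for

The basic timing of walking — cycle duration and its split into stance and
swing — is set by spinal rhythm-generating circuits that integrate
supraspinal drives with sensory feedback from the limbs. A lateral
hemisection cuts all supraspinal pathways on one side of the cord. The
resulting prediction problem: how should cycle, stance and swing durations
of the two hindlimbs change across treadmill speeds, in tied-belt (equal
belt speeds) and split-belt (unequal) conditions, when one side of the
network loses its descending drive but keeps its sensory feedback?

`hemigait` implements a computational model that answers this, plus the
analysis pipeline to compare its predictions with (synthetic) experimental
step-cycle data:

* **Circuit model** — per side, a rhythm generator made of flexor (F) and
  extensor (E) half-centers with persistent-sodium (NaP) dynamics

  `C V' = -gNaP m(V) h (V - ENa) - gL (V - EL) - gE (V - EsynE) - gI (V - EsynI)`

  coupled through inhibitory relays (InF, InE), and across the midline
  through commissural pathways (V0D and V2a→V0V→Ini crossed inhibition,
  V3-F/V3-E crossed excitation). Supraspinal drives α (flexor side,
  following belt speed) and γ (extensor side, constant) activate the
  network; stance-gated sensory feedback SF-E1 (hip-flexor stretch ramp,
  slope = belt speed) and SF-E2 (extensor load) closes the loop, attenuated
  by presynaptic inhibition `max(0, 1 - kPSI α)` from the ipsilateral drive.
  A right hemisection zeroes the right-side drives — nothing else — which
  releases right-limb feedback to full gain.
* **Simulation engine** — fixed-step RK4 (C++ core) of the closed loop with
  per-limb stance/swing state machines; speed sweeps for tied-belt and both
  split-belt protocols.
* **Phase analysis** — threshold-based phase-event extraction, step-cycle
  tables (cycle/stance/swing/duty), stance-swing crossing speeds, and the
  state-machine / flexor-driven / half-center regime classifier.
* **Synthetic experiment** — a generator of balanced repeated-measures cat
  datasets (5-6 cats x 2 states x speeds x 2 sides x cycles) with
  configurable hemisection effects.
* **Statistics** — a two-factor (state x speed) repeated-measures ANOVA
  (with `tidy()`/`glance()` methods) and a qualitative sign-agreement
  report between simulated and data-estimated hemisection effects.

## Worked example

Simulate the hemisected model with the ipsilesional (right) hindlimb on a
fast belt and the contralesional hindlimb on the slow belt:

```r
library(hemigait)
library(dplyr)

net <- build_network("hemisected")
net
#> <cpg_network> condition: hemisected
#>   populations: 20 (4 bursters, 16 relays)
#>   connections: 44 (12 crossed, 5 zero-weighted)

sim <- simulate_gait(net, betaL = 0.4, betaR = 1.0)
step_cycles(sim) |>
  group_by(side) |>
  summarise(cycles = n(), cycle = mean(cycle_s), stance = mean(stance_s),
            swing = mean(swing_s), duty = mean(duty))
#>   side  cycles cycle stance swing  duty
#> 1 left      62 0.640  0.329 0.311 0.514
#> 2 right     61 0.640  0.209 0.431 0.327
```

Both hindlimbs stay locked to one common cycle (0.64 s), but the
ipsilesional limb on the fast belt now spends only 33% of the cycle in
stance: its swing (0.43 s) exceeds its stance (0.21 s), the model's
signature of hemisection with the injured limb on the fast belt. Sweeping
the fast belt shows where this inversion starts:

```r
sw <- run_sweep("hemisected", "lsrf", beta_step = 0.05)
find_crossing_speed(sw, "right")
#> [1] 0.544
autoplot(sw)
```

On the statistics side, generate a synthetic cat experiment and test the
state effect on right-hindlimb swing in the same protocol:

```r
d <- generate_cat_dataset(effect_config(), seed = 1)
rm_anova(filter(d, protocol == "lsrf"), dv = "swing", side = "right")
#> Two-factor (state x speed) repeated-measures ANOVA: swing duration, right hindlimb
#>   6 cats x 2 states x 6 speeds
#>       effect df1 df2        ss        ms statistic   p.value
#>        state   1   5 0.1313747 1.314e-01 10203.468 1.803e-09
#>        speed   5  25 0.0132561 2.651e-03   155.921 5.237e-18
#>  state:speed   5  25 0.0002968 5.936e-05     5.131 2.255e-03
```

The swing duration is longer after hemisection (state effect, P << 0.05)
and shortens with the fast-belt speed, with a small state x speed
interaction — the same qualitative pattern as the simulation above.
`compare_sim_experiment()` turns both routes into a per-cell sign table and
match flags.

## Package layout

* `R/` — network construction, the limb/feedback model, the sweep driver,
  phase analysis, the synthetic-data generator, statistics and plotting.
* `src/engine.cpp` — the RK4 integrator for the closed-loop system.
* `vignettes/hemigait-methods.Rmd` — the model, its assumptions, the
  calibration choices and their limitations.
* `tests/testthat/` — unit, property and protocol-level tests, including
  oracle checks of the integrator (closed forms, step halving) and of the
  ANOVA (independent `aov()` error-stratum fits).
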