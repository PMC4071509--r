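---
title: "Modelling critical transitions in tumour metabolic symbiosis"
author: "metabogame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling critical transitions in tumour metabolic symbiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabogame)
```

## The biology and the game

Tumours are metabolically heterogeneous ecosystems.  Cells in the hypoxic
domain ferment glucose to lactate (the Warburg phenotype); cells near the
vasculature can instead respire the lactate those fermenting cells export
— the reverse Warburg effect, implemented physiologically by the lactate
shuttle (MCT1/MCT4 transport).  The two subpopulations thereby divide the
labour of ATP production, a *metabolic symbiosis* that favours tumour
growth under nutrient limitation.

`metabogame` treats the two subpopulations as the two players of a 2x2
normal-form game whose payoffs are ATP yields per encounter:

* `G_h` — ATP from glucose in a hypoxic cell (default 2, the net yield of
  anaerobic glycolysis per mol glucose),
* `G_o` — ATP from glucose in an oxygenated cell,
* `L` — ATP from lactate in an oxygenated cell (default 36, the oxidative
  yield of the 2 mol lactate produced from one glucose).

When both populations chase glucose they share it (`G_h/2`, `G_o/2`); a
hypoxic cell playing lactate earns nothing (it cannot respire lactate);
an oxygenated cell playing lactate earns `L` only while the hypoxic
population ferments, since fermentation is the only lactate source:

```{r game}
g <- build_symbiosis_game(metabolic_yields(G_h = 2, G_o = 36, L = 36))
g
pure_nash(g)
```

Measured yields satisfy `L > G_o/2`, and under that condition the game has
exactly one pure Nash equilibrium — hypoxic cells on glucose, oxygenated
cells on lactate, with payoffs `(G_h, L)`.  The equilibrium *is* the
observed symbiosis.  `G_o` itself is rarely reported for tumour cells; the
package default of 36 (the same aerobic yield per glucose as per 2 lactate)
is an explicit, configurable modelling choice, and every result that
depends on it can be rerun at other values through
`metabolic_yields()` or a YAML config.

## Dynamics: replicator selection plus Boltzmann exploration

Real tumours do not sit at the pure Nash vertex: hypoxic cells exhibit a
*range* of glycolysis levels.  The package therefore evolves mixed
strategies `x` (hypoxic) and `y` (oxygenated) under coupled
replicator-exploration dynamics

$$\dot x_i = x_i\big[(Ay)_i - x^\top A y\big]
  + T_x\, x_i \sum_j x_j \ln\frac{x_j}{x_i},$$

and symmetrically for `y` with payoff matrix `B` and rate `T_y`.  The
first term is classical replicator selection — strategies grow in
proportion to their ATP advantage; the second is an exploration
(mutation) flux whose temperature-like rates `T_x, T_y` stand for the
genomic/epigenetic instability of each population.  The exploration term
is the unique form whose interior rest points are exactly the Boltzmann
(logit) distributions $x_i \propto e^{(Ay)_i/T_x}$ — the fixed points
inherit the quantal-response structure that also underlies Q-learning
dynamics.  At `T = 0` the stable rest points are Nash equilibria; as
`T -> Inf` strategies randomise to uniform.

Properties the implementation maintains and the test-suite asserts:

* both simplices are invariant (`sum(dx) = sum(dy) = 0` analytically);
* for `T > 0` the flow points inward near the boundary, so the boundary
  is repelling and interior analysis suffices;
* at `T = 0` the field reduces exactly to two-population replicator
  dynamics.

## Locating equilibria

Interior fixed points solve the mutual self-consistency system
`x = boltzmann_response(A y, Tx)`, `y = boltzmann_response(B x, Ty)`.
`find_fixed_points()` solves this system rather than the raw vector
field: it is better conditioned and its roots are exactly the interior
equilibria.  Numerically the search runs in *logit* coordinates
`z = (logit(x1), logit(y1))`, for two reasons:

* near-vertex roots at small `T` have probability coordinates within
  machine epsilon of 0/1 but perfectly representable logits of order
  `max|payoff|/T`;
* in `z` the system is `z - R(z)` with `R` a smooth bounded map, so a
  damped Newton iteration (step-halving on the residual norm) converges
  from essentially anywhere.

Multi-start coverage uses an 11x11 grid on `[0.02, 0.98]^2` plus 50
seeded random starts, a contraction-map pre-pass, deduplication at
`1e-6`, and a parity retry (an even root count for this 2-D system
signals a missed saddle, so midpoints are re-polished).  Roots are
refined to self-consistency residual below `1e-12` and classified by the
eigenvalues of the analytic reduced Jacobian; `|Re(lambda)| < 1e-8`
gives the `marginal` label, which occurs exactly at folds and is excluded
from branch counting.

```{r fps}
find_fixed_points(g, exploration_rates(Tx = 2, Ty = 0.5))
```

## Critical transitions, basins, and the phase diagram

Sweeping one exploration rate (`sweep_bifurcation()`) produces the
bifurcation structure of the symbiosis: for the default stoichiometry at
`Ty = 0.5`, growing `Tx` moves the oxygenated population from a
monostable high-lactate-respiration state, through a bistable window
(two stable states separated by a saddle whose stable manifold is the
basin boundary, `basin_map()`), to a monostable high-glucose state.
Fold positions are detected as stable-count changes between adjacent
grid values and refined by bisection to a parameter tolerance of `1e-4`
(`refine_fold()`); fold detection by count change was preferred to
eigenvalue continuation because it is robust in 2-D and needs no
branch-switching logic.  Quasi-static forward/backward tracking
(`hysteresis_loop()`, `therapy_path()`) occupies different branches
inside the window — the hysteresis signature that makes these
transitions *critical*: once the occupied branch folds away, the state
jumps discontinuously and does not return when the parameter is
restored.

`phase_diagram()` maps the `(Tx, Ty)` plane into zones: `bistable`
cells (two stable equilibria), and monostable cells classified by
`classify_coupling()` as `strong` when at least half of *each*
population plays its symbiotic action (`x_glucose >= 0.5` **and**
`y_lactate >= 0.5` — the stricter both-populations reading of
"at least half of the tumour cells participate") or `weak` otherwise.
Therapy that perturbs instability rates or breaks the lactate shuttle is
then a path through this diagram; `therapy_path()` flags the step at
which the occupied attractor disappears (a forced critical transition,
jump threshold 0.2 in `(x1, y1)` distance, mimicking quasi-static
dosing).

## Study conditions and numerical choices

The default study conditions, used by the test-suite and chosen once:

* yields `G_h = 2, G_o = 36, L = 36`;
* 1-D sweeps: 201 log-spaced points, `Tx` in `[0.5, 8]` at `Ty = 0.5`
  (and `Ty` in `[0.05, 4]` at `Tx = 2`) — ranges bracketing the bistable
  window, which an initial coarse scan of the self-consistency map
  located around `Tx` in `(1.8, 2.4)` at `Ty = 0.5`;
* phase diagram: 61x61 log-spaced grid on `[0.5, 8] x [0.05, 4]`;
* basins: 21x21 interior grid of initial conditions.

Integration uses adaptive Dormand-Prince (deSolve, `rtol = 1e-9`,
`atol = 1e-12`), with components clamped at `1e-12` before log terms —
harmless because the boundary is repelling for `T > 0`.  Convergence is
declared on the field norm, not state stagnation.  Two tolerance
subtleties are deliberate:

* `basin_map()` accepts a field norm of `1e-8` (not `1e-10`): the
  integrator's local error bounds the attainable terminal field norm near
  `|J| * rtol * |state|`, and with attraction rates of order the payoff
  scale a `1e-8` field norm already pins the state well within the
  `1e-4` attractor-matching tolerance.
* The high-`T` uniformisation law is `|x1 - 1/2| ~ gap/(4T)`, where
  `gap` is the payoff difference between the two actions (for the
  default game, up to 9 for the oxygenated population).  Closeness to
  uniform at a given tolerance therefore requires `T` of order
  `gap/(4 tol)`, not a fixed multiple of the maximum payoff.

All randomness (random starts, random games, basin jitter) flows from
one user seed fanned out into named substreams, so identical
config + seed reproduce outputs byte-identically (timestamps can be
suppressed).

## What the generated games do and do not emulate

Property tests draw random bimatrix games (`random_game()`) with i.i.d.
uniform payoffs.  These exercise the solver far outside the symbiosis
geometry — saddles, near-degenerate folds, decoupled populations — and
so are good stress tests of root-finding, stability classification and
the odd-root-count parity.  They do not emulate real tumour data: no
measurement noise, no finite-population drift, no spatial structure, and
payoffs constant in time.  Passing them shows the machinery is correct
for the model class, not that the model captures any particular tumour.

## Limitations

* Two populations, two actions; glucose/lactate supply and vasculature
  held constant; no lactate toxicity threshold, glutamine/lipid
  metabolism, or angiogenesis.
* `T` is an input; the package does not estimate instability rates from
  microsatellite data.
* No pseudo-arclength continuation or codimension-2 analysis; fold
  locations come from count-change bisection on a user grid, so folds
  narrower than the grid spacing would be missed.
* Basin boundaries are resolved only to the initial-condition grid.
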