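---
title: "Models and methods behind anttrails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind anttrails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
```

```{r setup, message = FALSE}
library(anttrails)
```

anttrails studies how a foraging ant colony self-organizes into pheromone
trails. It contains three coupled layers: a stochastic lattice model of
individual ants, a macroscopic chemotaxis PDE for ant densities, and a
linear-stability layer that predicts, from a space-averaged version of the
PDE, which parameter combinations allow trails to form at all. This
vignette describes each model, the numerical choices made, and what the
test suite does and does not demonstrate.

## The stochastic lattice model

Ants are `n` point particles on an `M x N` lattice with a designated nest
site and `K` food-source sites. Each ant is either a *forager* or a
*carrier*:

* Foragers perform a Moore-neighbourhood random walk. Before any food has
  been found the walk is unbiased (each of the up-to-8 in-bounds neighbours
  is equally likely). Once pheromone is present, a neighbour at
  concentration difference `dc = c(neighbour) - c(here)` receives weight
  `epsilon` if `dc < 0`, `1` if `dc = 0`, and `1 + dc` if `dc > 0`;
  probabilities are weights renormalized over the neighbourhood. The small
  down-gradient weight `epsilon` keeps ants from freezing on local maxima:
  at a strict local maximum all neighbours tie at `epsilon` and the walk is
  again uniform.
* A forager that steps onto a food source becomes a carrier. Carriers make
  a beeline for the nest: each move enters the neighbour first crossed by
  the ray from the current cell centre in the homing direction. On arrival
  at the nest the carrier reverts to a forager.

The pheromone concentration `c(x, t)` obeys a reaction-diffusion equation
discretized by forward Euler with the 5-point Laplacian: diffusion `D`,
evaporation `gamma`, and deposition by each carrier into its occupied cell
at rate `A_dep * exp(-(d/sigma_decay)^2)`, where `d` is the carrier's
Euclidean distance to the food source (summed over all sources by
default). Deposition therefore fades rapidly as a carrier walks home —
the chemical signal is strongest around the food itself, and diffusion
spreads it into a plume whose gradient foragers can climb. The field uses
Robin ("Fourier-type") boundaries, `D dc/dn = -c` on each outer face, so
pheromone keeps flowing down its gradient across the boundary; ants
themselves reflect (their neighbourhood is simply restricted to in-bounds
sites) so the colony size is conserved.

Scheduling follows an event loop: one unit of time is `n` ant-move events,
each moving one uniformly chosen ant (with replacement). Once any food
source has been discovered, `round(1/dt)` field steps per unit of time are
interleaved evenly among the events, each batch executed *before* the ant
event it precedes, so the field is always current when an ant samples it.
Everything is driven by one seeded generator: a `(config, seed)` pair
reproduces a run bit for bit.

### Design choices in the lattice model

* **Homing direction.** The default (`beeline = "adaptive"`) recomputes the
  direction `x0 - pos` each step, which provably shrinks the Chebyshev
  distance to the nest by exactly 1 per move, so a carrier converting at
  Chebyshev distance `d` reaches the nest in exactly `d` moves (the test
  suite checks every trip of full runs). The literal alternative
  (`beeline = "fixed"`) extends the fixed vector `x0 - x_f`; it coincides
  with the adaptive rule on the exact nest-food ray but can drift past the
  nest from off-ray positions, so it is shipped only as an option.
* **Ray tie-breaks.** A ray leaving a cell exactly through a corner (45
  degrees) takes the diagonal neighbour; this keeps the contraction
  property deterministic.
* **Stability.** The forward-Euler field step requires
  `D*dt/dx^2 <= 1/4`; configurations violating it are rejected at
  construction, not at run time. The standard parameter set
  (`D = 10`, `dt = 0.001`, `dx = 1`) gives 0.01, far inside the bound,
  and also keeps the field nonnegative.
* **Multiple occupancy** is allowed — ants are points and do not exclude
  each other.
* **epsilon** defaults to 0.001 (the detection/exploration weight is only
  constrained to `0 < epsilon << 1`); the two-source equilibria reported
  below are insensitive to it across `1e-4`–`0.05`.

### Shipped scenarios

Three presets on a 50 x 50 lattice with a central nest mirror the three
canonical experiments: `one_food` (one source 15 sites away, `n = 500`,
`T_max = 300`), `two_equidistant` (two sources 15 sites away on opposite
sides), and `two_unequal` (sources 10 and 15 sites away in perpendicular
directions). The two-source presets use `n = 1000` ants — trail
coexistence is a large-population phenomenon; with few ants the pheromone
supply of a trail fluctuates too much to sustain it.

```{r one-food}
run <- simulate_lattice(scenario_preset("one_food", seed = 1))
glance(run)
trail_metrics(run)
```

After discovery (here around `t = 37`) the colony condenses onto the
nest-food corridor: ~99% of all ants end up within 3 sites of the segment.

### What the two-source dynamics do — and do not — reproduce

With two equidistant sources both trails persist indefinitely (neither
pheromone bump can die: near a source its own gradient always dominates,
at any amplitude, because the move weights depend on the *sign* of the
concentration difference, not its magnitude). The split of traffic
between the two trails is however not symmetric instant by instant: the
stronger trail channels roughly 80–85% of the foragers leaving the nest,
and which trail is the stronger one is decided by early stochastic
discovery (it flips between seeds). With sources at unequal distances the
proximal trail always wins the majority (~75–80% of corridor carriers),
but the distal trail survives at a reduced share rather than dying out
completely, for the same sign-not-magnitude reason. These equilibria are
remarkably robust: they barely move across `epsilon` in `[1e-4, 0.05]`,
population 500–1000, run lengths up to 5000 units, distance gaps of 1–10
sites and domains up to 100 x 100. A model variant in which
sub-threshold concentrations are imperceptible would be needed for
complete winner-take-all convergence; that lies outside the present move
rule.

## The macroscopic PDE

The continuum layer evolves a forager density `p`, a carrier density `q`
and a pheromone field `u`:

* `p`: diffusion `alpha * Lap(p)`, chemotactic drift
  `-chi * div((grad u) p)`, conversion to `q` at the food sources and back
  at the nest (rates `Omega_pq`, `Omega_qp` through mollified point
  masses);
* `q`: advection `-nu * div(v q)` with `v = (x0 - x)/||x0 - x||` the unit
  homing vector (`v = 0` at the nest itself);
* `u`: diffusion `D`, decay `gamma`, source `A_dep * q * exp(-||x - x_f||^2)`
  summed over sources (decay length 1, as the continuum source is
  conventionally written; note this differs from the lattice's
  `sigma_decay` parameterization).

`p` and `q` carry homogeneous Neumann boundaries so the total ant mass
`integral(p + q)` is conserved; `u` carries the same Robin closure as the
lattice field. Initial data: `p` a mollified point mass at the nest,
`q = u = 0`.

### Numerics

Diffusion is advanced by Peaceman–Rachford ADI (two implicit 1-D
tridiagonal solves per step, unconditionally stable, second order);
advection by first-order conservative upwind with zero-flux boundary
faces (CFL `nu*dt/h <= 1` enforced at construction); the chemotaxis term
by explicit conservative face-flux differencing; conversions explicitly,
evaluated for both `p` and `q` from the same pre-step fields so the
exchange cancels exactly and mass is conserved to rounding error
(~1e-13 over 1e4 steps in the tests). The update order within a step is
`u`, then `q`, then `p`, so freshly deposited pheromone drives the same
step's chemotaxis. Dirac masses are discretized as raised-cosine bumps of
radius `delta_width` (default `2h`), normalized to unit discrete
integral; a radius below the grid spacing degrades gracefully to a
single-cell indicator. Divergence (mass blow-up or non-finite values)
aborts with a diagnostic rather than returning garbage.

Default problem sizes (50 x 50 cells, `h = 1`, `dt = 0.01`) were chosen so
that a full qualitative run — discovery, trail ridge, quasistationary
two-trail states — completes in seconds; the convergence test verifies
that halving `h` and `dt` shrinks the error against the analytic heat
kernel at the expected rate, so finer grids are a matter of budget, not
correctness.

## Linear stability of the space-averaged system

Averaging the conversion and source coefficients over the domain turns
the PDE into a constant-coefficient system amenable to plane-wave
analysis. Its homogeneous equilibrium is

```{r equilibrium}
ap <- averaged_params()
homogeneous_equilibrium(ap)
```

with `Gamma = (MN)^-2 (1/Omega_pq + 1/Omega_qp)^-1` and
`E(x_f)` the product of error-function differences arising from
integrating the Gaussian deposition kernel over the rectangle. The
identity `MN (p_h + q_h) = 1` holds to machine precision, and in the
limits `Omega_pq -> 0`, `Omega_qp -> Inf`, `E -> 0` the no-food
equilibrium `(1/MN, 0, 0)` is recovered.

Perturbing with plane waves `exp(i k.x + lambda t)` yields a 3 x 3 linear
system; requiring a nontrivial solution gives a cubic dispersion relation
for `lambda(k)`. The cubic's coefficients are assembled from the matrix
invariants and solved with `polyroot()`; an eigen-decomposition of the
negated linear part is kept as a fallback (and as an independent oracle in
the tests). At `k = 0` the cubic factors exactly into roots
`{0, -(Omega_pq + Omega_qp)/MN, -gamma}`.

```{r dispersion}
res <- max_growth_rate(averaged_params(), k_grid(0.05, 51))
glance(res)
autoplot(res)
```

A positive maximum over a low-wavenumber window is the signature of trail
onset; high wavenumbers are always damped by diffusion.

### Why the default stability parameters differ from the continuum defaults

The averaged system is only unstable when the chemotactic feedback loop
(carriers deposit -> pheromone gradient -> forager flux -> more carriers)
beats forager diffusion and pheromone decay at low `k`. Expanding the
constant cubic coefficient shows the window opens iff
`alpha * gamma < chi * A_dep * pi * E(x_f) / (8 (MN)^2)` (for equal
conversion rates), so for fixed rates the domain must not be too large.
The package defaults — `chi = 10`, `A_dep = 5`, `M = N = 15`, the
pheromone parameters at their standard values — satisfy this comfortably
and place the default dispersion surface in the trail-forming regime,
which is the regime of interest for the parameter sweeps; with the
continuum layer's neutral `chi = 1`, `A_dep = 1` the window closes for
any domain above ~6 x 6. Every parameter is overridable, and the sweep
results (stabilization by `D` and `gamma`, destabilization by `A_dep`,
near-independence of `nu`) are monotone trends that do not depend on this
baseline choice.

```{r sweeps}
parameter_sweep("D", c(5, 10, 20, 40), averaged_params(), k_grid(0.05, 41))
```

## Trail metrics

There is no canonical quantitative definition of "a trail has formed", so
the package uses explicit artifact definitions and reports their
parameters. `corridor_occupancy()` is the fraction of ants (or density
mass) within `half_width` (default 3 lattice units, matching the visual
width of simulated trails) of the nest-source segment;
`winner_index()` normalizes per-corridor carrier counts over carriers in
any corridor, excluding stragglers. Carrier counts measure standing
stock, not flux: a trail twice as long holds twice the carriers per unit
of traffic, which slightly flatters distal trails in the winner index.

## What the synthetic scenarios do not capture

The model deliberately omits finite food reservoirs, births and deaths,
terrain-dependent hopping, ant-ant exclusion, orientation/turning
dynamics and nest-marking pheromones. Passing tests therefore demonstrate
the self-organization mechanism — chemotaxis plus directed return — under
idealized conditions, not quantitative agreement with any particular ant
species; all concentrations, times and lengths are dimensionless model
units.
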