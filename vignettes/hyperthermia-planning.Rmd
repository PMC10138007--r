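---
title: "Bioheat modelling and injection-site planning with thermoplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioheat modelling and injection-site planning with thermoplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoplan)
```

## The physical model

Magnetic-nanoparticle hyperthermia heats a tumor by exposing injected
nanoparticles to a low-frequency magnetic field.  Treatment succeeds when the
whole tumor reaches the necrosis threshold (43 °C is the conventional value)
while as little of the surrounding healthy tissue as possible does.

`thermoplan` models the tissue temperature `T(x, t)` (°C) on a cubic domain
`Ω = [0, L]^3` with the modified Pennes bioheat equation

    ρc ∂T/∂t = ∇·(k ∇T) + ω_b ρ_b c_b (T_a − T) + Q_m + Q_r,

with zero heat flux (`k ∇T · n = 0`) across all six faces and a uniform
initial temperature.  The terms are conduction, the blood-perfusion exchange
with arterial blood at `T_a`, metabolic heat `Q_m`, and the external heating
`Q_r` deposited by the nanoparticles.  Pennes' classical assumptions apply:
heat exchange with blood happens in capillaries, perfusion is isotropic, the
vascular geometry is not resolved, and capillary blood arrives at the body
core temperature.  That last assumption is why the package defaults to
`T_a = T_init = 37` °C: with core and capillary temperature identified there
is no reason for the arterial temperature to differ from the initial tissue
temperature.

Each of the `Np` injections contributes a radially symmetric Gaussian
specific absorption rate (SAR),

    Q_r(x) = Σ_i A exp(−‖x − x0_i‖² / r0²)   [W/m³],

where `A` is the peak volumetric heating and `r0` the coverage radius; both
are set by the amount of ferrofluid injected at a site and are treated as
fixed treatment parameters.  Contributions superpose, the source is
time-independent (injection sites do not move during a session), and the
Gaussian is evaluated over the whole domain without a cutoff radius —
exactness is preferred over a micro-optimization that would change the far
tail.

### Parameters and defaults

The default parameter set, used by the three built-in validation scenarios,
is the standard soft-tissue set from the hyperthermia-modelling literature:

| parameter | unit | healthy | tumor |
|---|---|---|---|
| `k` (conductivity) | W/(m·°C) | 0.51 | 0.64 |
| `omega_b` (perfusion rate) | 1/s | 5.0·10⁻⁴ | 1.25·10⁻³ |
| `rho`, `rho_b` (densities) | kg/m³ | 1000 | 1000 |
| `Q_m` (metabolic heat) | W/m³ | 420 | 4200 |
| `c`, `c_b` (specific heats) | J/(kg·°C) | 4200 | 4200 |
| `A` (SAR peak) | W/m³ | 0.08·10⁶ | — |
| `r0` (SAR radius) | m | 1.9·10⁻² | — |

Sessions last `t_end = 3000` s (50 minutes) with a time step `ht = 0.1` s on
a `N = 128` interval mesh (`h = L/N`, `L = 0.1` m).  Useful closed forms for
orientation: a space-uniform healthy domain relaxes to
`T_a + Q_m/(ω_b ρ_b c_b) = 37.2` °C with time constant
`ρc/(ω_b ρ_b c_b) = 2000` s; homogeneous tumor tissue relaxes to 37.8 °C
with time constant 800 s.  Both are used as solver tests.

## Discretization

The solver is an explicit forward-time central-space (FTCS) scheme on the
node-centred grid `x_i = i·h`, `i = 0..N` per axis (`(N+1)³` nodes).  The
medium is piecewise homogeneous, so the conductivity at a cell face is the
harmonic mean of the two adjacent nodal values, which preserves flux
continuity across the tissue interface.  The update has convergence order
`O(h², ht)`; both orders are verified empirically in the test suite (a
manufactured steady problem for space, the uniform exponential solution for
time).

Design choices where the discrete formulation was genuinely open:

* **Boundary stencil.**  Zero-flux faces are realized by mirror nodes: a
  missing neighbour `T(−h)` is replaced by `T(+h)`, independently per axis
  at edges and corners.  This keeps the one-sided normal derivative centred
  (second order) and is the conventional discrete counterpart of the Neumann
  condition.
* **Tumor membership.**  A node belongs to the tumor when
  `‖x − center‖ ≤ radius` for any tumor sphere — ties on the surface count
  as tumor, the conservative choice when the goal is ablating the whole
  tumor.
* **Per-node fields.**  `ρc` is assembled per node even though the default
  tissues share one value; the stepper never assumes homogeneity.
* **Stability guard.**  The explicit scheme requires
  `ht ≤ h² ρc / (6 k_max + h² (ω_b ρ_b c_b)_max)`; with the default
  parameters and `N = 128` the bound is ≈ 0.667 s, so the reference
  `ht = 0.1` s is comfortably stable.  `simulate_treatment()` refuses larger
  steps unless forced, and aborts with a diagnostic if non-finite values
  appear.
* **Precision and determinism.**  All arithmetic is double precision and the
  kernel is sequential, so repeated runs are bit-identical.

Internally the C++ stepper embeds the grid in a one-node ghost layer
(refilled by mirroring each step) and sweeps a single reference stencil
wherever a node and its six neighbours carry the majority (healthy) tissue
parameters; tumor nodes, interface nodes and any node deviating from the
reference are kept in a sparse correction list holding their exact per-face
coefficients.  The reference-node arithmetic is the same expression as the
literal stencil, so the optimization changes no result beyond ordinary
floating-point re-association of the source terms; equality with a literal
triple-loop transcription is asserted to 10⁻¹² in the tests.  The Gaussian
SAR term is evaluated in separable per-axis factors inside the sweep; the
explicit-array code path must agree with it to near machine precision, and a
test checks that too.

## Damage metrics and the planning objective

Damage is scored on the final field only (a session's outcome is evaluated
at `t = t_end`): a node is damaged when `T ≥ T_damage` (inclusive, 43 °C by
default).  `Nt` and `Nh` are the damaged percentages of tumor and healthy
nodes respectively (node counts within each mask), and `β = 1` exactly when
every tumor node is damaged.  The planning objective is

    O(p) = 300 − Nt − (100 − Nh) − 100·β,

minimized over the injection coordinates `p`.  The definition is chosen so
that `O` reduces exactly to the healthy-damage percentage `Nh` whenever the
tumor is fully ablated — only that reading makes the objective a meaningful
penalty (an untouched domain scores 200, the ideal plan 0), so `Nh` is
always interpreted as healthy *damage*, not as the undamaged fraction.  No
thermal-dose integration (CEM43, Arrhenius) is attempted; see Limitations.

## The differential-evolution planner

`optimize_injections()` searches the `3·Np`-dimensional box `[0, L]` per
coordinate with best/1/bin differential evolution:

* population `3·Np × pop_multiplier` individuals (default multiplier 35),
  initialized uniformly;
* mutation `V = X_best + F (X_a − X_b)` with `a, b` distinct and different
  from both the best and the target individual;
* binomial crossover with constant `C`; as printed, a pure binomial rule can
  return the target unchanged when `C → 0`, so one uniformly chosen
  coordinate is always inherited from the mutant (the standard convention;
  disable with `force_mutant_index = FALSE` for the literal rule);
* greedy selection with ties favouring the trial;
* stopping when the population objective spread satisfies
  `sd(O) ≤ atol + tol·|mean(O)|` (population standard deviation), or after
  `max_generations` (default 10,000), in which case the attempt is flagged
  unsuccessful rather than raising an error.

`F` and `C` are free parameters of the method; the defaults — `F` dithered
uniformly in `[0.5, 1]` once per generation, `C = 0.7`, `atol = 0`,
`tol = 0.01` — are the common practice for best/1/bin and are exposed in
`de_settings()`.  Out-of-bounds trial coordinates are clipped to the domain
(injections must stay inside tissue).  Because the objective is a pure
function of the coordinates, identical candidates reuse cached objective
values.  Elitism (the population best never worsens) follows from greedy
selection and is asserted in the tests.

## Built-in scenarios and the synthetic generator

`builtin_scenario(1..3)` provide the three validation geometries: one
centred tumor (one injection), two tumors on the cube diagonal (two
injections), and three tumors (three injections for the naive plan; for
this geometry the planner does better with two — placing `np = 2` is the
recommended configuration, as a third site tends to be pushed to the domain
border where it is useless).  The naive baseline plan always injects at the
tumor centres (`tumor_centers()`).

`random_scenario()` is a first-class fixture generator for property-style
tests: reproducible for a fixed seed, it places non-overlapping spheres with
a boundary margin and the default tissue parameters.  What it emulates is
the geometry variability of the validation scenarios — what it does *not*
emulate is anything anatomical: no irregular tumor shapes, no heterogeneity
within a tissue, no vasculature, no skin convection.  Tests passing on these
fixtures therefore validate the numerics and the planning machinery, not
clinical realism.

## Problem sizes used by the tests

The routine test suite verifies the discretization on small grids (5³ for
the stencil oracle, up to 17³ for symmetry and convergence checks), runs the
planner end-to-end on a coarse 32-interval mesh with a 10 s step, and runs
the full-fidelity reference mesh (`N = 128`, `ht = 0.1` s) only for the
scenario-level reproduction checks.  The 256-interval refinement run takes
on the order of an hour on one core and lives in
`scripts/grid_independence.R`, intended as a nightly job; the routine suite
carries a 64-vs-128 refinement-trend check instead (healthy damage within
0.5 percentage points, a bound implied by the observed 0.04-point change
from 128 to 256 and the scheme's `O(h²)` spatial order).

## Numerical corner cases

* `ht = 0` in `pennes_step()` is the identity, useful for plumbing tests.
* An empty injection set is allowed and simulates the unheated baseline.
* A scenario with no tumor makes `Nt` and `β` undefined;
  `damage_fractions()` errors unless `allow_empty_tumor = TRUE`.
* Scoring thresholds are compared inclusively (`T ≥ T_damage`), so a node
  sitting exactly on the threshold counts as damaged.
* The CSV results table writes a zero `SD` footer for a single run rather
  than `NA`, keeping the layout stable.

## Known limitations

* Thermal damage is a binary threshold on the final temperature; no
  Arrhenius kinetics, CEM43 dose, or time-delayed necrosis.
* Perfusion is constant — no temperature or damage dependence, no vascular
  architecture.
* Tumors are spheres; no image-derived geometry.
* The SAR model is a fixed isotropic Gaussian per injection; nanoparticle
  transport and anisotropic distributions are out of scope.
* The optimizer treats evaluations sequentially; no parallel population
  evaluation.
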