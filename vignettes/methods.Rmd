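---
title: "Stage-structured consumer–resource models with multiple resource use: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-structured consumer–resource models with multiple resource use: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichestates)
```

## The model family and its assumptions

`nichestates` analyses one consumer population split into juveniles (`C_J`)
and adults (`C_A`) that exploit different sets of resources. Three structural
assumptions are made throughout, and everything else follows from them:

1. resources renew logistically (rate `r`, carrying capacity `K`), or — for
   allochthonous subsidies — by donor control `dR/dt = I − lR`;
2. all trophic interactions are linear (mass action, rate `a`, conversion
   efficiency `b ∈ (0, 1]`);
3. maturation (juvenile → adult) and reproduction (adult → juvenile) are
   proportional to the juvenile and adult food intake respectively, and each
   stage suffers constant background mortality `d`.

Assumption 3 creates the feedback of interest: the two stages are coupled
only through the maturation and reproduction flows, so the juvenile and
adult resource compartments interact like apparent competitors. Three
scenarios vary the resource structure: independent *additional resources*
per stage; *multiple habitats* per stage, with recruitment flows pooled over
source habitats and split evenly (factor `1/n`) across destination habitats
— the even split is our reading of colonisation as a purely random process;
and *interstage sharing*, where each stage also consumes the other stage's
major resource at cross rates `a_JA`, `a_AJ`.

The state vector is always ordered resources first (juvenile-side, then
adult-side), then juvenile classes, then adult classes, so serialized
trajectories are comparable across runs.

## From isoclines to a cubic

At a coexistence equilibrium the resource equations give
`R* = K(1 − aC/r)` per resource (jointly,
`R_J* = K_J(1 − (a_JJ C_J + a_AJ C_A)/r_J)` under sharing, since both stages
deplete each resource; subsidies give `R* = I/(l + aC)`). Substituting into
the adult balance `dC_A/dt = 0` and the total balance `d(C_J + C_A)/dt = 0`
yields two zero-net-growth isoclines. In the multiple-habitat scenario the
total balance is taken over all habitat classes
(`n_J dC_J + n_A dC_A = 0`); at a symmetric equilibrium any combination of
the per-habitat balances vanishes, and this choice is the one that keeps the
juvenile isocline a clean quadratic carrying the habitat ratio `n_A/n_J`.

For the first two scenarios both isoclines are upward-convex quadratics
through the origin; composing them and dividing out the trivial root leaves
a cubic `F(C_J*) = Λ1 C_J*³ + … + Λ4` whose positive real roots are the
candidate equilibria — hence at most three. Under sharing the isoclines are
rational (quadratic over increasing linear); clearing denominators before
factoring the trivial root gives a cubic again. Coefficients are obtained by
dense polynomial composition (exact convolution arithmetic), not symbolic
algebra, and `eval_cubic()` exposes the polynomial for verification. The
test suite checks the roots against an independent oracle that intersects
the isoclines by dense sampling and bisection, at 1e-6 relative tolerance.

## The bistability condition, and what it does and does not guarantee

`ass_condition()` declares alternative stable states possible when the cubic
discriminant
`Δ = 18Λ1Λ2Λ3Λ4 − 4Λ2³Λ4 + Λ2²Λ3² − 4Λ1Λ3³ − 27Λ1²Λ4²`
is positive (three distinct real roots) **and** every root maps to a fully
positive equilibrium. Positivity is checked root by root, so both signs of
`Λ1` are handled uniformly. Two positivity variants are exposed:

* `require_resources = TRUE` (default): juveniles, adults and all resources
  strictly positive — interior coexistence in the strict sense. A subsidy
  channel with zero input is identically empty and exempted.
* `require_resources = FALSE`: juvenile and adult positivity only. A root
  whose mapped resource abundance is negative corresponds to a state in
  which that resource is over-exploited to dynamic extinction. This relaxed
  reading is the one under which *strong two-sided* resource sharing
  recovers alternative states: once both cross rates are large the stages
  have exchanged their major resources, and the recovered states each
  exclude the minor resource. Simulation confirms those states are genuine
  attractors (e.g. `a_JA = a_AJ = 0.3` at `K = 15`). The scenario-3 region
  map therefore uses the relaxed condition; the strict condition, by
  construction, can only lose cells.

Two further facts matter for interpretation, both established numerically
by this package's own dynamics module:

* **The condition is necessary, not sufficient.** With purely linear
  interactions, the juvenile-dominated root frequently sits at a strongly
  depleted juvenile resource, where the consumer–resource oscillation is
  barely damped; the equilibrium is then a weakly unstable focus
  (`λ_max ≈ +0.05` at the reference rates) with no surrounding stable
  orbit, and trajectories spiral out into the adult-dominated basin. This
  was verified in log-coordinates at tolerances `1e-10/1e-12` over 20,000
  time units, which tracks the exponentially small resource crashes
  exactly. Genuine stable–unstable–stable configurations do occur (they
  are common at unequal stage death rates, and appear within ±50% of the
  sharing-scenario reference rates), and the acceptance suite demonstrates
  two attractors by simulation at exactly such a point.
* **Agreement between the analytic condition and brute-force attractor
  counting is therefore partial.** The corresponding acceptance check
  reports the measured agreement (about 0.9/0.7/0.6 across the three
  scenarios at the reference jitter) rather than asserting equivalence.

## Parameters

All rates refer to the reference parameterisation `default_params()`:
`r = 1` (per time; sets the time unit), `a = 0.1` (per abundance per time),
`b = 0.5` (dimensionless), `d = 0.1` (per time), carrying capacities 10
(additional resources and habitats) or 15 (sharing) with weak cross rates
`a_JA = a_AJ = 0.01`. Axis ranges for the region maps extend to roughly
three times the reference capacities (`K` up to 30) and to cross rates 0.45;
the reference figures print the sampled values, not plot limits, so the
ranges were fixed once to cover the qualitative pattern and are ordinary
function arguments.

## Dynamics, attractors, clustering

`integrate_model()` and `find_attractor()` use `deSolve::ode` (lsoda,
`rtol = 1e-8`, `atol = 1e-10`). `find_attractor()` integrates a transient of
up to 2,000 time units in chunks of 250, stopping early once the right-hand
side is numerically stationary, then measures over a 500-unit window.
Classification: relative amplitude below `1e-4` → fixed point; sustained
bounded oscillation → periodic orbit; all consumer classes below `1e-6` →
boundary (consumer-free) state; drifting window averages → non-converged,
excluded from counts. Attractors are compared by their **time-averaged
state** (relative tolerance `1e-2`, absolute floor `1e-6`), which is what
distinguishes juvenile- from adult-dominated states whether they are points
or cycles; phase is deliberately ignored. Abundances below the extinction
floor `1e-9` are clamped to zero between chunks — at abundances that small a
population is extinct, and carrying them as `1e-30`-scale numbers would let
spurious "atto-scale" rescues decide basin membership.

The default initial-condition grid places resources at carrying capacity and
crosses total juvenile and adult abundance on a log-spaced grid over
`[1e-2, 2 max K]`. For habitat models, `allocations = "corners"` adds
strongly asymmetric juvenile splits; without them symmetric dynamics can
never reach the habitat-asymmetric attractors.

## Scans and the heterogeneity search

`scan_ass_region()` evaluates either the analytic condition (fast; used for
the region maps) or attractor counting (brute force) on a rectangular
parameter grid; cells where either fails record the error rather than
aborting the scan. Discriminants with `|Δ| < 1e-12 · max|Λ|⁴` are flagged
`boundary` and excluded from area fractions. The heterogeneity search fixes
two habitats per stage and sweeps a juvenile productivity difference
`K_J ± δ`, preserving the total — isolating heterogeneity from total
availability, which the balance criterion says matters separately. At
`δ ∈ {0, …, 4}` it finds three attractors: one adult-dominated state and two
mirrored juvenile-dominated states in which either juvenile subpopulation
dominates (with its local resource dynamically extinct). The mirrored pair
already exists at `δ = 0` by spontaneous symmetry breaking; heterogeneity
keeps it over a finite `δ` range and breaks its exact mirror symmetry.

## The fixture generator

`generate_fixture_params()` jitters every rate of a scenario's reference set
by independent uniform factors in `1 ± 0.5` (efficiencies capped at 1),
leaving structural fields fixed. It emulates "plausible parameter sets near
the reference conditions" for property tests — nothing more: draws are
independent, uniform, and uncorrelated across rates, so passing tests say
nothing about correlated or far-from-reference parameterisations, and the
structural assumptions (linear interactions, two stages, logistic renewal)
are never varied. All randomness flows through one explicit seed and the
global RNG state is restored afterwards.

## Numerical choices

Cubic roots come from `polyroot`; complex pairs with relative imaginary part
below `1e-8` count as real; roots closer than `1e-9` (relative) are merged
and flagged non-hyperbolic. Candidate equilibria must reproduce
`|rhs| < 1e-8` (scaled) before being reported. Stability labels use the
largest real part of the finite-difference Jacobian spectrum with a `1e-6`
dead band for non-hyperbolicity. Degenerate parameter sets whose reduced
polynomial drops below cubic degree are solved at their effective degree.
For non-integer habitat numbers (the analytic branch of the habitat
scenario) no finite-dimensional state exists, so records carry `NA`
stability and are verified on the isocline relations instead. Subsidised
parameter sets make the reduced equation non-polynomial; equilibria are then
located by dense isocline intersection (4,000-point grid plus bisection).

Problem sizes used by the test and acceptance suites — 50×50 analytic
planes, 100 fixtures per scenario for the oracle equivalence, 50 points per
scenario for the agreement check (3×3 initial grids), 4×4 initial grids at
the bistable point, two offsets with 27 runs each for the heterogeneity
search — were chosen so each suite completes in minutes on a single core
while leaving every qualitative pattern clearly resolved.

## Known limitations

* Linear functional responses and food-proportional stage transitions are
  structural; saturating responses, interference, adaptive niche-shift
  timing and individual growth are out of scope.
* The analytic condition counts cubic roots; it does not classify
  stability, so its green regions overstate dynamic bistability (see
  above). Conversely the strict-positivity variant misses alternative
  states that exclude a resource.
* Attractor counting sees only what its initial-condition grid reaches;
  exotic attractors with thin basins may be missed.
* No global bifurcation continuation: region boundaries are resolved only
  to grid resolution.
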