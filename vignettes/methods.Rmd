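---
title: "Models and methods behind switchscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind switchscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchscape)
```

`switchscape` compares three quantitative readouts of commitment in a
bistable mass-action network — the saddle-node (fold) location of the
deterministic dynamics, the mean first-passage time (MFPT) of the
volume-scaled Markov jump process, and the quasi-potential barrier height
from large-deviation theory — and the parameter-sensitivity spectra each
induces. This vignette records the models, the numerical choices, and the
reasoning behind the design decisions, in the package's own words.

## The network model and its two dynamical readings

A network is a list of species with initial concentrations (nM), an
ordered list of mass-action reactions of total reactant order ≤ 2 (plus a
declared trimolecular extension used only by the Schlögl fixture), a
positive parameter table, one designated *input parameter* (the control
axis; in the apoptosis-like setting, the initiator-caspase level `cas8`,
which enters as a constant-concentration catalytic modifier) and one
*output species* (the pore-forming tetramer analogue).

From a single reaction table the package derives both dynamical readings:

* the deterministic field `dx/dt = b(x) = Σ_j ν_j ã_j(x)` over intensive
  rates `ã_j` (`k`, `k x_i` times any modifier level, `k x_i x_j`,
  `k x_i²`, `k x_i³`), and
* the jump process over molecule counts `X ≈ ω x`, with propensities
  `ω k`, `k X_i`, `k X_i X_j / ω`, `k X_i (X_i − 1) / ω`,
  `k X_i(X_i−1)(X_i−2)/ω²`.

No symmetry factor of ½ is applied to homodimerisation propensities: the
two conventions differ only by a rescaling of the rate constant, and the
package follows the convention in which the deterministic term is
`k x²`. The scale `ω` (molecules per nM) is tied to a cell volume `V` in
µm³ by `ω = V · 6.02214×10²³ · 10⁻⁹ · 10⁻¹⁵ ≈ 0.602 V`; `ε = 1/ω` is the
large-deviation small parameter. Time is left in the unit implied by the
rate constants ("model time unit"); no conversion is attempted because
none of the quantities compared depends on the choice.

Counts are initialised as the nearest integer of `concentration × ω`.
Modifiers are parameters rather than species because the control input is
held fixed along every analysis axis; making it a species would force a
conservation law the analyses would immediately undo.

## Deterministic analysis

Fixed points come from multi-start damped Newton iterations on `b(x) = 0`
with the analytic mass-action Jacobian (finite differences are avoidably
noisy exactly where they matter, near the fold). Starts combine log-spaced
rescalings of the initial state, endpoints of short stiff relaxations
(which find the attractors essentially always), and seeded log-uniform
random states; roots are deduplicated at 10⁻⁶ relative radius and
classified by Jacobian eigenvalues: no positive real part → stable, exactly
one → saddle (the transition state; this covers the one-dimensional middle
state), more → unstable. The Newton residual tolerance is 10⁻¹⁰ on a scaled
infinity norm.

The saddle-node location is found by bisection on the *number* of
coexisting fixed points (3 inside the bistable window vs 1 outside),
refined to 10⁻⁵ relative bracket width, with warm-started refinement of
the previous step's roots. An extended defining system (`det J = 0`)
would converge faster per step but brings its own bordering machinery;
with a single control parameter the count bisection is simple, robust and
easily fast enough, and the diagram itself is produced by
natural-parameter continuation with solution reuse.

## Stochastic simulation and first-passage times

`ssa_run()` is Gillespie's direct method, exact by construction, in
compiled code; tau-leaping and other accelerations are deliberately
absent because the first-passage tails are the object of study. The
sampler uses R's RNG, and every run in an ensemble is seeded as
`master seed + run index`, so ensembles are bit-reproducible and
independent of execution order. In `arrhenius_estimate()` the per-size
seed is keyed to the size value itself, making the per-size estimates
invariant to the order in which sizes are listed.

A first-passage event is the output species count first reaching
`ceiling(f × high-state output count)` with `f = 0.8` by default; the
ceiling respects integer counts and strict crossing. Runs still below
threshold at the horizon are censored: counted, reported, excluded from
the mean. The default horizon is 100× the deterministic transit time from
just past the saddle to the threshold (computed by event-detecting
integration); for far-from-fold conditions where the MFPT dwarfs any
transit time, pass an explicit `t_max`. Sensitivity analyses of the MFPT
reuse one master seed across all parameter perturbations (common random
numbers), which cancels most Monte-Carlo noise out of the ±2 %
differences.

`exact_mfpt_birth_death()` solves the first-step recursion of a
birth-death chain in closed form (`u_0 = 1/b_0`,
`u_n = (1 + d_n u_{n-1})/b_n`, summed from start to target) and is the
exact oracle against which the SSA ensemble is validated.

## The quasi-potential and the geometric method

The local quasi-potential `S(x; x_low)` is the minimum of the
large-deviation action over paths from the living attractor to `x`. The
Lagrangian of the jump process has no closed form, so it is never
evaluated: the package works entirely with the Hamiltonian
`H(x,p) = Σ_j ã_j(x)(e^{p·ν_j} − 1)` and the geometric (time-free) form of
the action. The per-segment cost of moving in direction `y` is

> ℓ(x, y) = max { p·y : H(x, p) ≤ 0 },

a convex program whose feasible set contains `p = 0` (so ℓ ≥ 0, and
drift-aligned motion is free). It is solved by a KKT Newton on
`μ ∇_p H = y, H = 0` with an analytic Hessian
`Σ_j ã_j ν_j ν_jᵀ e^{p·ν_j}`, warm-started along the path, and initialised
from the closed-form maximiser of the quadratic (Gaussian) approximation —
which is also the correct limiting answer at degenerate points where the
drift vanishes (fixed points along the path), so those points short-circuit
to the quadratic value instead of iterating a singular system.

The discrete action of a path `φ_0..φ_N` uses *Simpson quadrature per
segment* — ℓ at the left endpoint, midpoint and right endpoint of each
chord, weighted 1:4:1. A midpoint-only rule admits a genuine failure mode
found during development: the optimiser can "tunnel" a long chord across
an expensive region whose midpoint happens to be cheap, producing a
spuriously low discrete action that equal-arc reparametrisation then
exposes. With Simpson costs the one-dimensional barrier agrees with the
quadrature oracle to ~10⁻⁷ relative and the two-species barrier moves by
less than 0.1 % between 50 and 200 path points.

The outer loop alternates (a) equal-arc-length reparametrisation with (b)
bounded quasi-Newton (L-BFGS-B) descent of all interior points against the
discrete action, using the envelope gradient `∂ℓ/∂x = −μ ∂H/∂x` at the
maximiser. The *optimised* path, not the re-interpolated one, is the
reported result. Convergence is declared when the relative action change
and the displacement *normal* to the curve (tangential sliding is pure
reparametrisation gauge) fall below `tol` (default 10⁻⁴), or when no
improvement beyond `tol` has occurred for five consecutive cycles — the
alternation has a small noise floor, and demanding much more than the
10⁻³-level discretisation accuracy would be false precision. Paths are
initialised through the saddle: a straight segment in the model
coordinates up to the saddle, then the deterministic flowline down to the
target attractor, so the descent branch starts at zero cost. In log-space
charts (`z = log x`, conjugate momentum `q = p x`; recommended when
species levels span decades, as in the apoptosis-like fixture) the state
floor (default 10⁻⁹ nM, 10⁻⁶ for the 20-species fixture) bounds the chart
from below.

The barrier is the maximum cumulative action along the low→high path; the
independently computed saddle should attain it, and `barrier_height()`
reports both. The two-well landscape profile glues the uphill branch
(cumulative action from the living state) to the reverse path's branch
(well depth of the death state), matched at the saddle and projected on
the output species, optionally on a log axis.

In twenty dimensions the minimisation is local: different initialisations
can settle into different path minima, especially far from the fold where
the barrier is large and the landscape is stiff. Barrier values for the
high-dimensional fixture are therefore reported with their convergence
flag, and the package's quantitative validation rests on the one- and
two-species fixtures where independent oracles exist.

## Arrhenius consistency

`log E[τ] → ω ΔS + const` as `ω` grows. `arrhenius_estimate()` regresses
log MFPT on ω. Over any finite ω window the regression slope carries a
prefactor drift of order `1/ω`; the committed Schlögl defaults (below)
were chosen so that the window ω ∈ {15, 20, 25, 30} leaves that drift at
the few-per-cent level, well inside the 15 % band the validation suite
asserts for the simulated slope against the geometric-method barrier.

## Sensitivity spectra

*Local spectra.* Every kinetic parameter is multiplied by `1 ± δ`
(default δ = 0.02) one at a time and the output functional re-evaluated.
The designated input parameter is excluded: for the fold-location output
it *is* the axis being measured, and keeping the key set identical across
output kinds is what makes the spectra comparable. The direction that
increases the output — right-shifts the fold, lengthens the MFPT, raises
the barrier — is labelled oncogenic (a higher barrier to death is the
oncogenic direction in the apoptosis reading), and its magnitude is the
ranking statistic. Perturbations that destroy bistability are flagged and
excluded from ranking with a warning.

*Sobol spectra.* A Saltelli paired-matrix design over per-parameter
ranges (default log-uniform from half to twice nominal — the sampling
space is an assumption, stated prominently, not a measured quantity),
with total effects by the Jansen estimator and bootstrap CIs. The base
sample comes from a Sobol low-discrepancy sequence generated in-package
(Gray-code construction, Joe–Kuo direction numbers, 21 dimensions,
verified point-for-point against an independent generator during
development), with a seeded digital shift for replication. Draws whose
model loses bistability are rejected and the whole cross-row set is
resampled from the continuation of the sequence; both accepted and drawn
counts are reported, and the indices are explicitly conditional on the
bistable region — a caveat, not a bug, since the comparison targets the
bistable regime.

*Comparison.* `spearman_rho()` uses rank correlation with average ranks
for ties (via `stats::cor.test`), and `compare_spectra()` assembles the
pairwise matrix that is the pipeline's headline deliverable.

## The packaged fixtures

**Schlögl** (`make_schlogl()`): `2X → 3X` (k₁), `3X → 2X` (k₂, the
trimolecular rate-law extension, namespaced so no other code path touches
it), `0 → X` (k₃, control), `X → 0` (k₄). The committed defaults
(k₁ = 6.95, k₂ = 1, k₃ = 4.257, k₄ = 12.385) place the fixed points at
0.45, 2.2 and 4.3 and the bistable pump window at k₃ ∈ (1.06, 6.58). They
were chosen once, using the exact birth-death oracle, so that the
validation window ω ∈ {15, …, 30} already sits in the Arrhenius regime
(exit barrier ≈ 0.18, fewer than ~10⁶ SSA events per switching run) while
keeping ≥ 7 molecules in the low state at the smallest size — a
compromise any desk-scale study of rare switching must make.

**Two-species shuttle** (`make_toggle2()`): the Schlögl species plus a
linear shuttle `X ⇌ Y`. The shuttle flux cancels at steady state, so the
fixed-point structure (and the fold) is inherited exactly, while the
transition path becomes genuinely two-dimensional — the minimal honest
test surface for the geometric method, validated against a graph-path
(`Y(X)` knots, Nelder-Mead) oracle.

**Synthetic apoptosis-like switch** (`make_apoptosis_synthetic()`,
packaged as `apoptosis_synthetic.json`): 20 species, 53 reactions, `cas8`
modifier input, `Bax4M` output. It emulates the structure of the
simplified mitochondrial apoptosis pathway — caspase-driven Bid
truncation, tBid-triggered Bax activation to the membrane with
recruitment feedback (`BaxM + Bax → 2 BaxM`), dimerisation and
tetramerisation into the pore species, Bcl2 sequestration of both tBid
and membrane Bax, and a linear downstream release cascade with no
feedback onto the core. All parameters are in-package design choices
(verified bistable for `cas8` roughly in (4, 17.5) at generation time),
**not** transcriptions of any published supplement; the fixture is
labelled synthetic for exactly that reason. Structural claims (species
and reaction counts, rate-law types, bistability, barrier decreasing
toward the fold, far-from-fold barriers much larger than near-fold ones)
are meaningful on it; numerical coincidence with any published
parameterisation is not.

## What the synthetic data do and do not show

The fixtures exercise every code path under conditions where independent
oracles exist (closed forms, exact chains, dense grid searches,
brute-force path minimisation, analytic variance decompositions). Passing
tests therefore demonstrate correctness of the numerics, not biological
fidelity: real pathway models bring rate constants spanning more orders
of magnitude, conservation laws, and far larger system sizes, where the
MFPT route becomes infeasible and only the deterministic and geometric
routes remain — which is precisely the regime the barrier/fold-location
comparison is for.

## Problem sizes used by the validation suite

The test suite and the acceptance script run at desk scale, chosen to
exercise the asymptotics without waste: 2,000 switching runs for the
SSA-versus-exact comparison at ω = 20; 400 runs per size for the
Arrhenius slope over ω ∈ {15, 20, 25, 30}; 100-point paths for
one/two-species barriers and 50–60-point paths for the 20-species
fixture; Sobol reference estimates at n_base = 1024 with 200 bootstrap
replicates; 10-point fold sweeps. Each choice is stated where it is used.

## Known limitations

* The geometric minimiser returns a *local* minimum-action path;
  high-dimensional, far-from-fold conditions can have competing path
  minima, and the convergence flag should be consulted.
* Sobol indices are conditional on the bistable region of parameter
  space; the rejection scheme changes the effective input distribution.
* The MFPT route degrades near-deterministically long switching times
  (censoring dominates); use the barrier route there — that asymmetry is
  one of the package's main points.
* Reactions of order ≥ 3 beyond the namespaced Schlögl extension, and
  non-mass-action kinetics, are out of scope.
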