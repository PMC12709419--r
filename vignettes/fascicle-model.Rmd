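---
title: "The fascicle compartment model: assumptions, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fascicle compartment model: assumptions, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fasciclesim` simulates the tissue-scale pharmacokinetics of local
anesthetics (LAs) in a single peripheral-nerve fascicle cross-section. This
vignette is the package's own account of the model: what is assumed, which
parameters matter, where the source description of the model left genuine design
freedom, and what the numerical results can and cannot support.

## The compartment network

The fascicle is a disc (default diameter 140 µm) tiled by a pointy-top
hexagonal lattice (pitch ≈ 1.874 µm, chosen so 5060 cells tile the disc).
Each cell is one compartment of exactly one kind:

* **Nerve fiber** — an axon plus its Schwann-cell sheath; the lipophilic
  reservoir. Fibers sit on the 1-in-4 sublattice (`q`, `r` both even).
* **ECF** — aqueous extracellular fluid, the diffusion medium.
* **Capillary** — an ECF-like cell with an additional first-order clearance
  sink; by default one central capillary plus six at radius `diameter/3`
  placed by exact 60° lattice rotation.

Because lattice site counts inside a disc change only in whole symmetry
orbits, no pitch yields exactly 5060 sites; the builder therefore trims the
five outermost ECF sites (largest radius, lowest id first) and demotes one
complete six-fold orbit of outermost fibers, which lands exactly on the
reference census of 1254 fibers, 7 capillaries and 3799 ECF cells. The trim
is the only six-fold-asymmetric feature of the default build; the untrimmed
build (`target_total = NULL`) is exactly symmetric and is what the symmetry
tests exercise.

State is the vector of per-compartment concentrations, dimensionless
relative to the external bolus concentration (≡ 1). Dynamics are linear and
time-invariant per phase: `dc/dt = A c + b`.

## Exchange rates and the whole-compartment convention

Three kinds of coupling enter `A`:

* **Aqueous hops** (ECF–ECF, ECF–capillary). A particle crossing from one
  cell center to the next travels `x` = one pitch; the mean first passage
  time of 1D diffusion over `x` is `x²/2D`, so the hop rate constant is
  `k = 2D/x²`. Only the component normal to the shared interface matters,
  which is what makes the 1D argument applicable on a 2D lattice.
* **Membrane exchange** (ECF–fiber). The tabulated conductances `k_EN`
  (ECF→fiber) and `k_NE` (fiber→ECF, µL/s) are lumped with the two
  center-to-membrane diffusion legs by reciprocal addition
  (`1/k* = (x₁² + x₂²)/2D + 1/k`); with the tabulated magnitudes the
  diffusion correction is below 0.01%, so the lumped pair preserves the
  equilibrium ratio `k_EN/k_NE` to four significant figures — which is
  exactly what the reference equilibrium concentrations (345.3, 97.5)
  require.
* **Capillary clearance**: a diagonal term `−Q/V` with
  `Q = velocity × cross-section × open fraction`. The default open fraction
  is 0.75 (about a quarter of capillaries are transiently closed by
  vasomotion), giving `Q = 1.96×10⁻⁵ µL/s`.

**The per-compartment convention.** The tabulated rate constants are
whole-compartment quantities: the membrane conductances refer to the whole
Schwann-cell surface and the mean-first-passage rate is a compartment's
total escape rate. The package therefore divides every pairwise rate by the
lattice coordination number (6), so that each of a compartment's six edges
carries one share. The alternative reading — the full constant on every
edge (`edge_rate_convention = "per_edge"`) — is implemented and exposed, but
it makes fibers act as lateral transport short-circuits: the through-fiber
conductance `k_EN/2` then exceeds the aqueous hop conductance more than
tenfold, the partitioning retardation of the diffusion front disappears, and
no volume calibration can reconcile the reference onset times with the
reference durations (onsets come out an order of magnitude too fast at any
slab depth that matches the washout). Under the per-compartment convention
both observables are consistent at a single calibration, which is why it is
the default.

**Fluxes and conservation.** Aqueous exchange is donor-volume weighted
(amount flux `k·c_donor·V_donor`), so volume-weighted mass is conserved
exactly by construction; membrane exchange uses the directional conductances
(`amount flux = k·c`). Fiber–fiber exchange does not exist (fibers are never
adjacent under the default pattern; the rule is a defensive error).

## Volumes: the 3:2 anatomy and the slab-depth calibration

A 2D model needs an axial thickness to turn cell areas (µm²) into the
volumes (µL) that divide conductances (µL/s). Two choices close the system:

* **Fiber volume scale.** Anatomically the fiber:ECF cross-section ratio in
  a fascicle is 3:2, while the cell census is 1254:3799; the default build
  therefore gives each fiber cell `1.5 × 3799/1254 ≈ 4.54` times the ECF
  cell volume, honouring the 3:2 total. This is not cosmetic: the fiber
  volume multiplies the reservoir capacity (volume × partition ratio) that
  retards the inbound diffusion front and sets the washout mass, and with
  equal cell volumes the onset and duration observables cannot be matched
  simultaneously by any slab depth.
* **Slab depth.** The single global calibration parameter, default 195 µm.
  It is fitted once (`calibrate_slab_depth()`, monotone root find) so that
  the lidocaine/physiological onset equals its reference value, and then
  frozen: every other drug, condition, and phase uses the same depth, so all
  cross-scenario comparisons are genuine predictions. At this depth the
  predicted washout half-times fall within ~16% of their reference values
  without any further adjustment — the acceptance script recomputes all of
  them.

## Boundary conditions and phases

* **Filling** (bolus influx): the fascicle is immersed in LA solution at
  unit concentration. The default implementation couples every *aqueous* rim
  cell to a fixed ghost reservoir through one hop-rate term per missing
  lattice neighbour — the standard finite-volume reading of a Dirichlet
  boundary that keeps all real cells dynamical. Rim *fiber* cells do not
  touch the bath: coupling them through the plain hop rate would pin them
  toward concentration 1, far below their partition equilibrium, and destroy
  the analytic equilibrium state. A rim-clamping variant
  (`boundary = "clamp"`) is available. Capillary clearance stays active
  during filling by default (`clearance_in_filling`); at the calibrated
  volumes its effect on the filling steady state is below 0.2%.
* **Voiding** (washout): zero-flux outer boundary (a fascicle embedded in a
  periodic array of fascicles), capillaries draining. The initial state is
  the *analytic* equilibrium — 1 in aqueous cells, the lumped conductance
  ratio in fibers — rather than the end of a long filling run, which removes
  any dependence on the filling horizon.

## Metrics

Onset: the first time more than 50% of fiber compartments exceed 50% of the
reference concentration, linearly interpolated on the fraction-vs-time
series between samples (interpolation removes the sampling-grid
quantization; whether the original analysis interpolated is not stated).
Duration (t½): the first time at least 50% of fibers fall below 50% of
their own initial equilibrium value. Thresholds use strict inequality for
onset (">50%") and non-strict for duration ("at least"), a measure-zero
distinction.

**Threshold reference.** The duration metric is explicitly
equilibrium-relative. For onset the package defaults to the same reference —
each fiber counted against half of its *own equilibrium* concentration
(`reference = "equilibrium"`) — and also implements the literal
external-unity reading (`reference = "external"`). The default was chosen
because fiber equilibrium concentrations are 12–345× the external
concentration, so against an absolute 0.5 threshold the crossing happens in
the leading diffusive tail within well under a second for every drug and
every volume calibration, and the cross-drug onset pattern collapses; only
the equilibrium-relative reading reproduces the reported onset set and its
fold-relations. The choice is a metric convention, not a change to the
dynamics, and both references are computed from the same trajectories.

## Numerical choices

* **Default integrator** (`"stiff"`): `deSolve::lsodes`, sparse implicit
  multistep, `rtol = 1e-8`, `atol = 1e-12`. The assembled system is stiff —
  membrane rates reach ~3×10³ s⁻¹ while washout evolves over 10³–10⁴ s.
* **Matrix-exponential path** (`"expm"`): the exchange network satisfies
  detailed balance, so `A` is similar to a symmetric matrix by an explicit
  diagonal weighting; one symmetric eigendecomposition then gives the exact
  solution at arbitrary times. Used as the cross-check on the full preset
  (metrics agree with the stiff path to <1%) and for long horizons.
* **Explicit reference** (`"rk"`): fixed-step classical Runge–Kutta with the
  step bounded at 1 ms; retained as the fidelity reference and for the
  step-halving convergence audit (halving the step moves metrics by <0.1%).
* **Sampling**: filling is sampled every 0.01 s for the first 60 s and every
  1 s after; voiding every 1 s (or 1/100 of the horizon). Metrics
  interpolate between samples.
* **Steady-state detection**: when no filling horizon is given, integration
  proceeds in doubling windows until `max|dc/dt| < 1e-6 × max(c)`.
* **Independent oracles in the tests**: closed-form single- and
  bi-exponential toys, a 1D diffusion chain with Fick scaling, and a dense
  Padé matrix exponential (`integrate_oracle`, limited to n ≤ 500) that is
  implemented independently of the spectral path it checks.

Problem sizes in the test suite were chosen to exercise every code path at
full fidelity where it matters (the complete 5060-compartment preset for the
acceptance metrics and the cross-method comparison) and small discs
(~230 cells, same pitch) for property audits.

## Known limitations

* A single uniform fiber population: no distribution of fiber diameters,
  myelin thickness, or per-fiber kinetics; no myelin-layer substructure.
* The source fascicle description is internally inconsistent in places
  (140 vs 120 µm diameter; fiber density and the 3:2 area ratio cannot both
  hold with 1254 cells in a 140 µm disc). The package follows the majority
  reading (140 µm, census-exact lattice, 3:2 by volume scaling); a 120 µm
  disc is available by configuration.
* Reproduction quality is uneven across conditions: with the slab depth
  calibrated on the lidocaine/physiological onset, the washout half-times
  and their acidosis fold-changes are reproduced closely, but the acidosis
  onsets deviate beyond 30% — the reported acidosis onset pattern does not
  follow any capacity- or transport-scaling reachable within this model
  family, which the acceptance tests record honestly as failures rather
  than absorb into extra tuning.
* Constant external concentration during filling (no injection-volume
  effects, convection, or time-varying gradients); no pharmacodynamics —
  concentration thresholds stand in for conduction block; no time-dependent
  resting potential; membrane rate constants are taken as given inputs, not
  derived from pKa or partition coefficients.

## Session info

```{r, eval = FALSE}
sessionInfo()
```
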