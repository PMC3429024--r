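---
title: "Modeling oxygen-dependent erythrocyte ATP release and its transport in capillary networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling oxygen-dependent erythrocyte ATP release and its transport in capillary networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcatp)
```

## The biology in one paragraph

Human erythrocytes release ATP when the oxygen saturation of their
hemoglobin falls. The released ATP binds endothelial purinergic receptors
and initiates a vasodilatory signal that is conducted upstream to the
arterioles, so red cells act as oxygen sensors that request more flow
exactly where saturation is low. The release pathway is a classical
G-protein cascade: desaturation activates the heterotrimeric G-protein Gi,
whose βγ subunit stimulates adenylyl cyclase to produce cAMP; cAMP
activates PKA, PKA activates CFTR, and active CFTR gates ATP efflux
through pannexin 1. cAMP is hydrolyzed by PDE3, and insulin — at
concentrations seen in pre-diabetes — raises PDE3 activity, which is how
hyperinsulinemia blunts low-oxygen ATP release. `rbcatp` implements this
cascade as a dynamic ODE model, couples its steady-state consequences to
an advection–reaction model of ATP transport in capillary networks, and
provides the perturbation scenarios (insulin, reduced Gi expression, PDE3
inhibition) that make the two models useful.

## The pathway model

Four state variables evolve: active G-protein `GPa`, `cAMP`, active PKA
`PKAa` and active CFTR `CFTRa`. Inactive forms follow from conserved
pools (`GPi = GP_total - GPa`, and likewise for PKA and CFTR). The input
is the desaturated-hemoglobin fraction `tHb(t) = 1 - sO2(t)`:

$$\frac{d\,GPa}{dt} = k_{GPf}\,GPi\,tHb^{\alpha} - k_{GPr}\,GPa$$

$$\frac{d\,cAMP}{dt} = AC_{base}
  + \frac{k_{cAMPf}\,GPa}{1 + k_{cAMPi}\,PKAa}
  - \frac{v_0\,PDE3_{rel}\,PKAa\,cAMP}{K_{PDE3} + cAMP}$$

$$\frac{d\,PKAa}{dt} = k_{PKAf}\,PKAi\,cAMP - k_{PKAr}\,PKAa$$

$$\frac{d\,CFTRa}{dt} = k_{CFTRf}\,CFTRi\,PKAa^{\beta} - k_{CFTRr}\,CFTRa$$

with ATP efflux $F_{ATP} = k_{ATPflux}\,CFTRa$. Active PKA feeds back on
cAMP twice — it inhibits production (the denominator of the synthesis
term) and accelerates Michaelis–Menten degradation. Both feedback
placements follow the published description of the pathway; the
structural choice is validated by the dynamic fingerprint it must
reproduce (see below). All rate constants are per second and all
concentrations are dimensionless, normalized to unit pool totals: the
model describes relative activation of an average pathway, not absolute
copy numbers, which is why release must be calibrated before comparison
with experiments (see "Calibration").

Two notational points in the published equation set were resolved as
follows, as the package's own reading: the cAMP balance is taken with
`AC_base` added (not subtracted) and with PKA feedback on both terms, and
the conservation relations are sums of active and inactive forms. With
these readings and the reference parameter set the model reproduces the
reported dynamic fingerprint — cAMP peaking near 51 ms and ATP flux near
157 ms after a 40 ms desaturation step to 15.7% saturation — which is the
evidence that the reconstruction is the intended one. Had it not been, the
alternative reading (feedback on degradation only) would have been the
next candidate; it was not needed.

### Numerical choices

* Integration uses `deSolve::lsoda` (stiff-capable) at `rtol = 1e-8`,
  `atol = 1e-12`. The CFTR exponent β = 6.3 makes that equation sharply
  switch-like, and the system stiffens when cAMP collapses after the
  stimulus.
* The stimulus is piecewise-constant saturation. The integrator is
  restarted at every protocol discontinuity, so a 40 ms pulse has exact
  square edges rather than solver-smoothed ones.
* Dense output is written every 0.5 ms and peak times are refined by a
  local quadratic fit through the discrete maximum, which locates peaks
  well below the output spacing.
* The initial condition is the all-zero state (a resting, fully
  oxygenated cell); there is no pre-equilibration because with
  `AC_base = 0` the fully saturated pathway is exactly at rest.
* Total release integrates `F_ATP` by the trapezoid rule from stimulus
  onset until the flux falls below 1e-6 of its peak (or the trajectory
  ends). Halving the integrator tolerances moves the integral by well
  under 0.1%.

### Calibration

The model yields release in arbitrary (pathway-relative) units. To
compare with measured release, the package anchors the 40 ms pulse to
15.7% sO2 at 11.8 nmol ATP per 4×10⁸ erythrocytes — the
insulin-free measured value — and scales everything else by that one
factor (`calibrate_release()`). An anchored monotone model cannot also
pass exactly through every other measured point; in particular the
measured 13.1 nmol at 21.6% sO2 exceeds the 11.8 anchor at a *higher*
saturation, so the model's 21.6% prediction is necessarily below 11.8 and
agreement there is approximate (the package computes ≈ −18%). Calibration
always uses `PDE3_rel = 1`, so perturbation scenarios (insulin, Gi
deficit) share the baseline scale.

```{r pathway, eval = FALSE}
traj <- simulate_pathway(pathway_params(), desaturation_pulse(0.157))
attr(traj, "peaks")        # cAMP ~51 ms, F_ATP ~157 ms
dose_response(pathway_params(), c(0.216, 0.413, 0.618))
gi_deficit_scenario(pathway_params(), 0.6)   # ~59% decrease
find_pde3_recovery(pathway_params(), 0.6)    # ~0.6
```

## The network transport model

Plasma ATP in a capillary segment obeys

$$(1-H_T)\,\partial_t [ATP] = -u(1-H_D)\,\partial_z [ATP]
  + H_T C_0 (1 - C_1 S) - \frac{2}{R} k_d [ATP]$$

where `u` is blood velocity, `H_T`/`H_D` tube and discharge hematocrit,
`R` the radius, `S` the local oxyhemoglobin saturation, `C0` and `C1` the
linear steady-state release law, and `k_d` the endothelial ecto-ATPase
degradation constant (a wall flux, hence the `2/R`). Defaults are
`C0 = 1.4e-9` mol/(s·cm³), `C1 = 0.891`, `k_d = 2.0e-4` cm/s. Saturation
enters as a *steady* field: either computed by a one-dimensional
convective O₂ balance (consumption apportioned to segments by lateral
surface area, red-cell-flux-weighted mixing at junctions) or prescribed
by the user per segment. The full 3D blood–tissue diffusion problem is
out of scope here by design: the ATP equation needs only `S(z)`, and in
networks of this size the computed profiles are nearly linear along the
flow, which a 1D balance captures.

### Numerical scheme and conventions

* First-order explicit upwind in space, marched in time from `[ATP] = 0`
  until stationary, with the time step set by a Courant number of 0.9 on
  the plasma advection speed `u(1−H_D)/(1−H_T)` plus the degradation
  rate. This scheme is positivity-preserving by construction.
* Each segment's axial grid (default spacing 2 μm) is stored in flow
  order. The file format's velocity sign records axial orientation —
  negative means counter-current, flow toward decreasing z — and solvers
  use the magnitude, so counter-current capillaries need no special
  casing.
* Junctions mix conservatively: converging concentrations are averaged
  weighted by plasma volumetric flow (for saturation: red-cell flux).
  The published model does not state its junction rule; flux conservation
  is the only physically consistent choice and is what the mass-balance
  tests verify.
* At 2 μm spacing the numerical steady profile of a uniform capillary
  matches the closed-form solution to about 0.2% (first-order convergence
  verified on a 8–4–2–1 μm ladder), and steady mass balance closes to the
  solver tolerance per segment and network-wide.
* Stationarity is declared when the largest per-step change falls below
  `1e-6` of the field maximum (checked every 25 steps). For this
  hyperbolic problem the field is essentially exact one transit time
  after the slowest path has filled.
* Units: cgs internally (mol/cm³), μM in all reported numbers
  (1 μM = 1e-9 mol/cm³); geometry in μm and velocities in mm/s at the
  interface.

### The conducted dilation signal

The network-level dilatory signal is the attenuated sum
$\sigma_{dilation} = \sum_i [ATP]_i\, e^{-(L-z_i)/\lambda}$ over
segments, with `[ATP]_i` the segment mean in mol/cm³, `z_i` the segment
midpoint projected on the arterio-venous axis, `L` the network span and
λ = 1 cm the conduction length. Since λ exceeds `L` by a factor of ~30,
the choice of `z_i` convention is numerically immaterial (< 4% from the
plain sum); it is nevertheless fixed and recorded in the result object.
σ is a reported measure only — the model contains no arterioles, so the
signal is never fed back into diameters.

### Insulin at the network level

Elevated insulin halves `C0`. With zero inlet ATP the steady problem is
linear and homogeneous in `C0`, so mean `[ATP]` and σ both fall by
exactly 50% — a geometry-independent prediction the tests verify to
solver tolerance. With the literature inlet concentration of 0.25 μM the
inlet-driven component is unaffected and the decrease is strictly between
0 and 50% (the published geometry gives 33%; the exact value depends on
the network).

## The synthetic network generator

The measured network that motivated the transport model (a reconstructed
rat extensor digitorum longus capillary bed: 208 cylindrical segments in
an 84 × 169 × 342 μm domain, 63% mean entrance saturation, tissue
consumption 1.5 × 10⁻⁴ ml O₂/ml/s, one counter-current capillary) is not
publicly archived, so the package ships a generator that reproduces its
*statistical* structure rather than its anatomy. `generate_network()`
builds parallel capillary tracks from the arterial to the venular face,
subdivided into ~28 μm segments, with thinner cross-connections between
neighboring tracks and one whole track flowing counter-current (entering
at the venular face — realized that way because a backward edge inside
the layered mesh would create a flow cycle). Flows are routed, not drawn:
plasma splits at diverging nodes in proportion to radius⁴ and red cells
follow a plasma-skimming rule (exponent 1.2), after which velocities and
hematocrits are derived from the routed flows. Conservation at nodes is
therefore exact, and a final uniform flow rescale pins the velocity
marginal mean to the spec value.

Distribution defaults — radius 2.5 ± 0.2 μm, velocity 0.35 ± 0.1 mm/s,
discharge hematocrit 0.20 ± 0.05, Fahraeus ratio `H_T/H_D = 0.8` — are
literature-typical for resting rat EDL capillaries; the measured
distributions are unpublished, and these placeholders are deliberately
conservative. One visible consequence: with these supply rates the
convective O₂ balance extracts only ~10 saturation points across the
domain, whereas the measured network spans 17–63%. Analyses that need the
published saturation range should use the prescribed linear profile
(63% → 17%) shipped in `reference_fixtures()`; the headline network
result (the exact 50% insulin decrease) is independent of this choice by
linearity. Identical spec and seed reproduce a network byte-for-byte,
and generation does not disturb the caller's RNG stream.

## What the synthetic tests do and do not show

Passing tests on synthetic networks demonstrate the solver's correctness
(oracle agreement, conservation, superposition, positivity) and the
geometry-independent predictions (50% scaling, σ ≈ Σ within 4%). They do
not certify the absolute mean concentrations of the measured network —
the reported 0.076 μM (normal release, zero inlet) depends on the
unpublished geometry and hemodynamics. The single-capillary closed form
with study parameters puts the concentration scale at
`R·H_T·C0(1−C1·S)/(2k_d) ≈ 0.077` μM for S = 0.63, so the package's
magnitudes are consistent with the published ones, but that is a
consistency check, not a reproduction.

## Problem sizes and runtimes

The standard pathway run integrates 2 s of simulated time at 0.5 ms
output (4001 points) in well under a second. Scenario scans (dose–
response grids, the PDE3 recovery root search) are tens of such runs.
The 208-segment network at 2 μm spacing has ~3300 grid points and
reaches steady state in a few thousand CFL steps, a fraction of a second
of wall time; the full four-solve insulin scenario takes a few seconds.
These sizes were chosen so every documented result can be recomputed
routinely during development.

## Known limitations

* Only the oxygen-dependent release pathway is modeled; shear-induced
  (same cascade, different trigger) and receptor-mediated release are
  excluded, as is pannexin-1 gating detail beyond proportionality to
  active CFTR.
* Most rate constants are not individually measured; the set is
  constrained jointly by release magnitudes and time scales, so
  individual values should not be over-interpreted.
* The transport model assumes ATP is well mixed across the lumen; if
  near-wall concentration is what endothelial receptors see, absolute
  signal levels would shift.
* Hemodynamics (velocities, hematocrits) are inputs, not solved; vessel
  diameters never respond to σ, so the model predicts signals, not flow
  redistribution.
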