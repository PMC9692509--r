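---
title: "Magnetophoretic olfactory targeting in a nasal airway surrogate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetophoretic olfactory targeting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnasal)
```

## The problem

The olfactory epithelium on the roof of the nasal cavity is the one place
where an inhaled drug can reach the brain without crossing the blood–brain
barrier, but it covers only about 8% of the nasal surface and purely
aerodynamic deposition there is well below 1%. One proposed remedy is to
load the drug on magnetite microparticles and steer them with a permanent
magnet held against the nose. `magnasal` simulates that idea end to end:
it builds a two-dimensional sagittal surrogate of the nasal passage, solves
the steady laminar airflow through it, evaluates the field of cuboid NdFeB
magnets in closed form, traces microparticles under Stokes drag and
magnetophoretic force, and scores each magnet protocol by the percentage of
released particles that deposit on the olfactory wall segment.

Three magnet placements ("protocols") are compared, all using a remanence
of 1.2 T with flux-density components (0, 0.771, 0.919) T in the sagittal
plane and magnet centers 5 mm from the septum plane:

1. a 1 cm × 1 cm × 4 cm bar parallel to the septum (long axis
   anterior–posterior),
2. the same bar rotated 90° about the septum normal,
3. a 5 cm × 3 cm × 0.2 cm plate flat against the septum.

## Geometry: the sagittal surrogate

Real airway geometries come from segmented CT scans; reproducing one is
deliberately out of scope. `build_surrogate()` instead generates an
idealized channel in the yz-plane (y anterior→posterior, z
inferior→superior): a nostril inlet at the bottom of a vertical vestibule,
a chamfered bend into a horizontal passage under the roof, and a narrower
nasopharynx duct descending to a zero-pressure outlet. The geometry is a
closed polygon with labeled segments (`INLET`, `OUTLET`, `OLFACTORY`,
`WALL`) plus a regular grid mask for the flow solver.

Key parameter choices, made once:

* **Inlet width 0.01 m.** A 2-D model cannot honor the 3-D nostril area of
  1.32×10⁻⁴ m²; the width is of the order of a single nostril and preserves
  the 0.5 m/s mean inlet speed, which is what the particle dynamics feel.
* **Olfactory fraction 0.08** of the total wall length, realized exactly as
  a roof sub-segment (slightly posterior of mid-roof, where the olfactory
  cleft sits). Requested fractions from 0.05–0.20 are honored to within
  one grid cell.
* **Outlet width 0.006 m.** Narrower than the inlet so that mass
  conservation accelerates the flow toward the nasopharynx, reproducing the
  qualitative speed ordering seen in airway CFD: slow near the olfactory
  roof, moderate in the mid-passage, fastest at the nasopharynx.
* **Grid spacing 0.001 m**, giving 10 cells across the inlet (a minimum of
  8 is enforced) and a 70 × 50 lattice.

What the surrogate does *not* emulate: turbinates and meatus folds, the
lateral (x) dimension, septal asymmetry, mucus. Tests passing on the
surrogate therefore validate the physics implementation and its qualitative
behavior, not patient-specific deposition numbers.

## Magnetostatics: closed-form cuboid fields

Instead of a finite-element solution, the field of each uniformly
magnetized cuboid is evaluated with the Coulombian (surface-charge) model:
each magnetization component `M = B_r/μ₀` charges the pair of faces it
crosses, and the field of a uniformly charged rectangle has the classical
closed form of corner-summed logarithm (in-plane) and arctangent (normal)
terms. `grad_H()` differentiates that expression analytically, so the
force needs no numerical differentiation. The expressions are valid inside
and outside the magnet; the principal arctangent branch carries the correct
solid-angle continuation across the charged faces (the center of a cube
magnet recovers the −M/3 demagnetizing field to machine precision).

Numerical choices:

* The magnet interior is the pure Coulombian model (μᵣ = 1); the nominal
  μᵣ = 1.05 of NdFeB is recorded on the `magnet` object but would require a
  boundary-value solve and perturbs the exterior field by at most a few
  percent.
* Points on an edge singularity of the logarithm terms are evaluated at a
  1 nm offset and flagged instead of raising an error, so a grazing
  particle cannot crash a trace. The logarithm arguments are clamped at
  the smallest positive double to keep rounding undershoot silent.
* The test suite pins the implementation to independent oracles: a
  Gauss–Legendre surface-integration of the charge model (relative error
  < 10⁻⁶), the point-dipole far field (< 1% at 10 edge lengths), symmetry
  and r⁻⁴ decay of the Jacobian, and divergence/curl-freeness at random
  exterior points.

## Airflow: steady incompressible laminar solver

`solve_flow()` solves the steady incompressible Navier–Stokes equations
(air at 36.6 °C enters only through ρ = 1.14 kg/m³ and η = 1.9×10⁻⁵ Pa·s)
with three boundary conditions: uniform normal inflow of 0.5 m/s at the
inlet, zero gauge pressure at the outlet, and no-slip walls. The inlet
Reynolds number is ≈ 300, safely laminar (inputs above Re = 2000 are
rejected).

The discretization is a staggered (MAC) finite-volume grid: first-order
upwind convection, backward-Euler implicit diffusion, and a pressure
projection, marched in pseudo-time to the stationary state. The three
sparse operators (two Helmholtz, one Poisson) are Cholesky-factored once,
so each pseudo-time step costs three triangular solves; convergence is
declared when the momentum residual falls six orders of magnitude below its
first-step value. Walls that cut the grid are stair-stepped (first
order); tangential ghost values enforce no-slip halfway between cell
centers, which recovers second-order wall behavior on grid-aligned walls —
the plane-Poiseuille oracle (centerline 1.5× mean, L2 profile error < 2%
at 64 cells across) is the regression test for this. Discrete
incompressibility is exact to solver precision, so inflow and outflow
fluxes balance to rounding.

## Particle tracing

Magnetite microparticles (radius 7.5 μm, density 5200 kg/m³) obey

$$ m_p \frac{dv_p}{dt} = \underbrace{-6\pi\eta R_p (v_p - v_f)}_{\text{Stokes drag}}
   + \underbrace{\mu_0 V_p \tfrac{3\chi_p}{\chi_p+3}(H\cdot\nabla)H}_{\text{magnetophoresis}} $$

with one-way coupling (particles never modify the flow), no gravity, no
Brownian motion, and no particle–particle interaction — all justified at
this particle size and loading. Because magnetite susceptibility is high,
the saturated high-χ force `3 μ₀ V_p (H·∇)H` is the default; the exact
form with user-supplied χ is available. The momentum relaxation time
τ = 2ρ_pR_p²/(9η) ≈ 3.42 ms is far below the ~1 s transit time, so the
motion is overdamped and particle velocity tracks
`v_f + F_m/(6πηR_p)` closely.

Integration is classical fixed-step RK4 with `dt = τ/20` (a guard refuses
steps coarser than τ/10) up to `t_max = 10` s. Particles are released at
rest, equally spaced on a horizontal line anchored to the inlet centerline
at protocol-specific heights (dz = 0.71 cm for protocols 1–2, 0.31 cm for
protocol 3); the nominal 1.5 cm line length is clipped to the duct with one
cell of clearance, since the 2-D nostril is narrower than the anatomical
nostril length that figure refers to. The simulation is planar: forces
use the full 3-D field evaluated in the plane x = dx (0.25–0.3 cm,
protocol-specific), and the lateral component of motion is dropped.

Termination is threefold and exhaustive: **DEPOSITED** on first wall
contact (center within one particle radius; the position is projected onto
the nearest boundary segment; no rebound — consistent with a sticky mucus
layer), **ESCAPED** through the outlet, or **SUSPENDED** at `t_max`.
Suspended particles count in the efficiency denominator, never the
numerator.

Because the magnetostatic field is time-independent, the in-plane force is
by default tabulated once on a 2×-refined copy of the domain grid and
interpolated bilinearly during stepping — the same solve-fields-then-trace
structure used by finite-element workflows, and two orders of magnitude
faster than re-evaluating the closed form at every RK4 stage
(`force_interp = FALSE` restores exact evaluation; deposit positions agree
within about one particle radius). Velocity sampling is bilinear on
cell-centered values with zero wall velocity in solid cells; during the
final partial step before contact, sampling is clamped rather than raising
an error. Halving `dt` moves deposition points by less than one particle
radius on the validation fixtures.

## Delivery efficiency and protocol comparison

`delivery_efficiency()` is the percentage of released particles deposited
on the olfactory segment. `compare_protocols()` runs all requested
protocols on one shared domain and flow field (the airflow is
magnet-independent, so it is solved once), enforcing the conservation
invariant DEPOSITED + ESCAPED + SUSPENDED = N for every row.

On the default surrogate the three protocols give 0%, 0% and 0% olfactory
efficiency with sharply different deposition patterns: protocol 1 traps
all 100 particles on the vestibule wall next to the bar-magnet edge where
the field gradient peaks; protocol 2 holds them suspended in a drift–flow
balance (the reference behavior for this layout is capture on the *lateral*
wall — an x-direction feature a sagittal model cannot produce); protocol 3,
whose thin plate produces a weaker and more extended gradient, lets
particles travel into the main passage and deposit along it or escape.
The reference 3-D CT-geometry result of 2% for protocol 3 is not
reproducible on an idealized 2-D surrogate and is not a target of the test
suite; what the package asserts instead are the analytic anchors, the
solver oracles, and the qualitative orderings (gradient maximal at the
magnet edge, flow slow at the olfactory roof and fast at the nasopharynx).

## Problem sizes used by the tests

The suite runs the default 70 × 50 surrogate once (flow plus all three
100-particle protocols), a 128 × 64 Poiseuille channel at Stokes-like
conditions, a 48 × 16 slow channel with a deliberately strong bar magnet
(12 particles) for deposition-convergence checks, and a grid-convergence
pair (50 × 38 vs 100 × 75) on a reduced surrogate. These sizes keep the
whole suite at a few CPU-minutes while leaving every physical regime
(overdamped relaxation, drift-dominated capture, advection-dominated
escape) represented.

## Known limitations

* Two-dimensional: no lateral motion, no turbinate structure; lateral-wall
  capture (protocol 2's reference behavior) is unrepresentable.
* First-order stair-step walls and upwind convection: wall shear and peak
  speeds carry O(h) error; grid refinement changes the peak passage speed
  by under 5%.
* Fixed-step RK4 without adaptivity; the τ/20 default is validated against
  closed forms but stiff force spikes very close to magnet edges rely on
  the deposition projection to terminate cleanly.
* Steady inhalation only; no breathing cycle, humidity, or mucociliary
  clearance.
* The Coulombian model ignores μᵣ = 1.05 self-interaction (≲ 5% exterior
  field perturbation) and any soft-magnetic material nearby.
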