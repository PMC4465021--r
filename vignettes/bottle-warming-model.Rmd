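---
title: "Modelling bottle warming: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bottle warming: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(milkwarm)
```

## The physical problem

Refrigerated human milk is commonly rewarmed by standing the bottle in a
hot water bath.  Because the bath of a typical electric warmer can run at
80 °C — twice the recommended feeding temperature of 40 °C — parts of the
milk can overshoot 40 °C long before the average catches up.  `milkwarm`
simulates this process so that the spatial temperature distribution inside
the milk, not just its average, can be followed over time.

The model system is axisymmetric: a cylindrical plastic bottle (wall and
nipple of a generic plastic), milk in the lower part of the bottle,
headspace air above the milk, and an annular gap of bath water around the
bottle.  The heater holds the bath's outer and bottom boundaries, and the
underside of the bottle, at the bath temperature throughout; every other
exterior surface loses heat to ambient air by Newton cooling with
coefficient $h = 10.45\ \mathrm{W\,m^{-2}K^{-1}}$.

## Governing equations

Temperature obeys an advection–diffusion equation in every domain $i$,

$$\frac{\partial T}{\partial t} + \mathbf{v}\cdot\nabla T = \alpha_i \nabla^2 T,
\qquad \alpha_i = \frac{k_i}{\rho_i c_{p,i}},$$

with the advective term absent in the solids.  The three fluids (milk,
headspace air, bath water) flow by natural convection, modelled as
incompressible Newtonian flow with the Boussinesq approximation,

$$\rho_i\left(\frac{\partial \mathbf{v}}{\partial t}
  + \mathbf{v}\cdot\nabla\mathbf{v}\right)
  = -\nabla P + \mu_i \nabla^2 \mathbf{v}
  - \rho_i \beta_i (T - T_0)\,\mathbf{g},
\qquad \nabla\cdot\mathbf{v} = 0,$$

where $T_0$ is a per-fluid reference temperature (default: that fluid's
initial temperature — 4 °C for milk and headspace air, the bath temperature
for the bath).  Temperatures are carried in °C throughout; only temperature
*differences* enter the physics (buoyancy, Newton cooling), so no Kelvin
conversion is needed.

Boundary and interface conditions: no-slip at every solid/fluid interface;
no-penetration with zero shear at the liquid/gas interfaces (milk surface,
bath surface), which are treated as flat and fixed; temperature and normal
heat flux continuous across all internal interfaces; a symmetry condition
on the axis $r = 0$.  The three fluid regions are separate lidded
compartments — they exchange heat but never mass.

## Geometry: what the inputs pin down and what they do not

The bottle presets are defined by milk volume, nominal total volume and
height (60 ml / 107 ml / 49 mm and 178 ml / 324 ml / 140 mm) — the
quantities a bottle's label states — but not by radii or wall
thicknesses.  `cylinder_scenario()` therefore models the
system as coaxial cylinders and solves the inner radius from the nominal
volume and height as a plain cylinder, $R = \sqrt{V/(\pi H)}$, preserving
exactly the quantities that control the thermal mass.  The remaining
lengths are package defaults, all overridable:

| parameter | default | note |
|---|---|---|
| wall thickness | 2 mm | typical molded bottle wall |
| bath annular gap | 5 mm | warmer well clearance |
| bath level | milk level + 10 mm | bottle "stands in" the bath |
| nipple cap | 4 mm plastic closing the top | no internal cavity resolved |
| ambient temperature | 18 °C | matches the air property reference point |
| gravity | 9.81 m/s² along $-z$ | |

Note that the 60 ml bottle's printed height (49 mm) and volume (107 ml)
imply a squat bottle, wider (53 mm bore) than it is tall.  The geometry
module follows the printed numbers; the consequences are discussed under
*Limitations*.

## Discretization

* **Mesh** — structured tensor-product grid in $(r, z)$ with grid lines
  snapped to every material interface, so no cell spans two materials and
  conjugate interfaces coincide with faces.  Spacing is near-uniform (no
  wall-normal grading is applied); the default target is ≈4300
  quadrilateral cells.  Cell volumes are exact annulus volumes $2\pi r_c\,\Delta r\,
  \Delta z$.
* **Space** — finite volumes, central (harmonic-mean) conduction fluxes,
  first-order upwind advection by default.  Upwinding makes the advection
  matrix an M-matrix, which is what guarantees that temperatures can never
  leave the range spanned by the initial and boundary values.
* **Time** — implicit BDF2 (backward Euler for the first step), default
  $\Delta t = 0.1$ s.  Note that BDF2, unlike backward Euler, is not a
  monotone scheme: with upwind advection the temperature field respects
  the $[4, 80]$ °C data range up to micro-under/overshoots at round-off
  scale ($\sim 10^{-5}$ °C observed), which is why the boundedness checks
  carry a 0.01 °C slack.
* **Pressure–velocity coupling** — SIMPLE-type segregated
  pressure-correction on a collocated grid with Rhie–Chow momentum
  interpolation to suppress checkerboard pressure modes.  Face mass fluxes
  are corrected directly from the pressure-correction solve, so discrete
  continuity holds to the solver tolerance on every committed step.

### Inner solvers and tolerances

Momentum and energy systems are solved by alternating-direction line
Gauss–Seidel (TDMA); the pressure-correction system (a symmetric positive
semi-definite five-point M-matrix, singular per fluid compartment with a
compatible right-hand side) by incomplete-Cholesky preconditioned
conjugate gradients with the per-compartment mean removed.  Within the
outer coupling iterations the inner solves run loose (5 % CG residual
reduction, energy to $10^{-7}$) — their accuracy is progressively
tightened on long outer loops so they never floor the outer residual —
and every step finishes with a tight pass: pressure to a scaled divergence
of $10^{-6}$ and energy to $10^{-12}$, which is what makes the
conservation and continuity guarantees hold per committed step.

The outer iteration contracts geometrically (observed ratio ≈0.75 at 4300
cells, ≈0.89 on a 4×-refined mesh); the ceiling of 200 iterations leaves
headroom for the slow start-up steps on fine meshes.  Under-relaxation
0.7 (momentum) / 0.3 (pressure) is used: probes at 0.9/0.5 destabilized
the impulsive start (bath at 80 °C suddenly facing a 4 °C wall), and
0.7/0.3 is robust across every configuration exercised by the tests.

## Verification strategy

The solver is trusted only through independent references, implemented in
the `oracles` module:

* transient slab conduction against the Fourier series solution
  (`slab_conduction_profile()`), including an observed spatial convergence
  order ≥ 1.8;
* the lumped-capacitance limit (Biot ≪ 1) against the closed-form
  exponential;
* a differentially heated cavity, checking the circulation direction
  implied by the sign of the buoyancy term;
* conservation: with all boundaries adiabatic and no flow, total enthalpy
  is conserved to $10^{-8}$ relative per step;
* refinement: `refined_reference_metrics()` re-runs a scenario with
  $f^2$ times the cells and $\Delta t / f$.

Run them all with `run_verification()`.

## What the synthetic scenario generator emulates

`random_scenario(seed)` draws physically valid warming problems — milk
volume 30–250 ml, bath 40–90 °C, initial contents 2–25 °C, wall 1–3 mm,
with radius and headspace sampled so every geometric invariant holds.  It
reproduces the *structure* of the study inputs (multi-domain axisymmetric
geometry, per-domain properties, tagged boundaries), which is what the
property tests need.  It does **not** emulate real-bottle shape variety
(shoulders, necks, textured bases), free-surface motion, evaporation, or
temperature-dependent properties; tests passing on these scenarios say
nothing about those effects.

## Problem sizes used by the test suite

The acceptance checks run both presets at the default resolution
(≈4300 cells, $\Delta t = 0.1$ s; 60 ml bottle to 420 s, 178 ml bottle to
600 s) — each completes in a few minutes on one CPU.  Refinement
insensitivity is checked by halving $\Delta t$ at fixed mesh and by
doubling the cell count at fixed $\Delta t$ for the 60 ml preset, and by
halving $\Delta t$ for the 178 ml preset; the unit-level convergence
checks (slab order, factor-1 identity) run on small problems in seconds.

## Limitations

* **Geometry underdetermination.**  Only volumes and heights define a
  preset; radii, wall thickness and bath size are package defaults.  The
  milk heating rate scales directly with the wetted wall area and the
  wall conductance, so absolute temperatures are predicted only as well
  as those defaults match the actual device.  The squat 60 ml bottle
  implied by its 49 mm height has little side area in contact with the
  bath; a taller bottle of the same volume warms substantially faster.
* **Laminar first-order transport.**  First-order upwinding adds numerical
  diffusion; thin near-wall plumes are smeared at the default resolution.
  The boundedness guarantee is bought at this price.
* **Flat, fixed interfaces.**  No free-surface motion or evaporation at
  the bath surface; condensation on the cold bottle is ignored.
* **Constant properties.**  All material properties are evaluated at a
  single reference state; over 4–80 °C water's viscosity alone changes by
  a factor of ~3, which modulates convection strength.
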