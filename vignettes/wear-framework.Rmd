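---
title: "A cross-shear and contact-stress dependent wear framework for knee replacements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cross-shear and contact-stress dependent wear framework for knee replacements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkrwear)
```

## The wear model

Polyethylene wear in a total knee replacement (TKR) is simulated with a
modified Archard law in which the wear volume per loading cycle is
proportional to contact area and sliding distance,

$$ W = A \, S \, C, \qquad \delta = S \, C, $$

with $W$ the volumetric wear (mm³), $A$ the contact area (mm²), $S$ the
sliding distance (mm), $\delta$ the nodal linear wear depth (mm) and $C$ a
non-dimensional wear coefficient. Unlike classic Archard models with a
constant wear factor, $C$ here depends on the two quantities that dominate
polyethylene wear at the articulating surface: the cross-shear ratio $CS$
and the non-dimensional contact stress $P/E$,

$$ C(CS, P/E) \;=\; a \left(1 - e^{-b\,CS}\right)
   \left(c + d\,(P/E)^{\,e}\right), $$

with default constants $a = 1.47\times10^{-9}$, $b = 116.21$, $c = 0.84$,
$d = 450.23$, $e = 1.49$ — the published surface fitted to multidirectional
pin-on-plate measurements of moderately cross-linked UHMWPE (GUR 1020,
5 Mrad) against polished CoCr. Two structural properties follow directly:
unidirectional sliding ($CS = 0$) produces zero wear, and wear grows
super-linearly with contact stress (exponent $\approx 1.5$).

### Cross-shear as a frictional-work ratio

Following the unified theory of wear and frictional work, every surface node
accumulates a symmetric $2\times2$ frictional-work tensor over one loading
cycle,

$$ M = \sum_k \mu \, p_k \, a \, \lvert ds_k \rvert \; \hat u_k \hat u_k^{\mathsf T}, $$

where $\hat u_k$ is the direction of the $k$-th tangential sliding increment
in the node's material tangent plane, $p_k$ the contact pressure, $a$ the
nodal area and $\mu = 0.04$ the friction coefficient. The principal
molecular orientation (PMO) is not defined operationally in the source
literature; this package adopts the eigenvector of the larger eigenvalue of
$M$ — the direction receiving the most frictional work — which is the
natural reading of the unified theory. The cross-shear ratio is then the
minor-eigenvalue fraction

$$ CS = \frac{E_{\text{cross}}}{E_{\text{total}}}
      = \frac{\lambda_{\min}}{\lambda_{\min} + \lambda_{\max}} \in [0, 0.5]. $$

$CS$ is invariant under rotations of the tangent-plane basis, 0 for
collinear sliding and 0.5 for isotropic sliding. The test suite checks the
eigen solution against an independent brute-force oracle that scans
candidate orientations on a 1° grid. A fully degenerate tensor
(λ equal) reports the first basis vector as PMO, deterministically.

Because the polymer (pin or insert) can itself rotate during a cycle,
increments are always expressed in the *material* frame of the polyethylene
part before accumulation — for the oscillating pin this frame rotation is
precisely what generates cross-shear under in-phase motion. For the
in-phase pin-on-plate trajectory
($x = \tfrac{L}{2}\cos 2\pi f t$, $\theta = A \cos 2\pi f t$) the
centre-point cross-shear has the closed form
$CS = \tfrac12\!\left(1 - \mathrm{sinc}\,2A\right)$, which reproduces the
published matrix values 0.087 (±30°), 0.022 (±15°) and 0.18 (±45°); the
±10° condition evaluates to 0.010, consistent with the narrative value of
0.01 reported for that condition.

## Contact: elastic foundation with equilibrium search

The finite-element contact stage of the original workflow is replaced by an
elastic-foundation (Winkler) model, the standard desk-scale substitute for
conforming implant contact. The pressure under a rigid counterface
penetrating a layer of thickness $h$ by $\Delta$ is

$$ p = \frac{(1-\nu)E}{(1+\nu)(1-2\nu)} \frac{\Delta}{h}, $$

with $E = 553$ MPa and $\nu = 0.32$ (compressive, "equivalent" values for
moderately cross-linked UHMWPE) and $h = 10$ mm, the insert thickness, by
default. Penetration is measured by vertical ray projection of each insert
vertex onto the lower envelope of the rigid surface (grid interpolation of
the structured counterface mesh), which matches the load axis and is robust
for conforming geometry. At every time step the solver finds the vertical
approach and the unconstrained adduction–abduction tilt such that the
pressure field balances the applied axial load to 0.1 % and the
varus–valgus moment about the medially offset load axis vanishes (damped
two-variable Newton with a first-touch reset when contact is lost; the tilt
is applied in small-angle form and clamped to ±0.15 rad).

For ball-on-flat configurations the layer thickness is the model's only
free constant; `calibrate_layer_thickness()` pins it to the Hertz solution
so that the foundation contact radius at the calibration load equals the
Hertz radius. The calibrated backend reproduces the Hertz contact area to a
fraction of a percent on the meshes used here, and the Hertz closed form
(`hertz_ball_on_flat()`) is kept as an independent oracle. At 500 N on the
63.5 mm ball the peak pressure is ≈33 MPa, inside the 30–40 MPa window
reported for TKR.

Contact areas of ball-type solutions are estimated from the second moment
of the pressure field ($a^2 = 3\,\langle r^2\rangle_p$ for the foundation's
paraboloid cap) rather than by counting loaded vertices; the moment
estimate is smooth under mesh refinement, which matters for the inverse
modulus procedure.

## Synthetic geometry

The proprietary implant shape is replaced by a parametric stand-in
(`implant_params()`): a bicondylar femoral component whose condyles are
barrels of constant distal radius (30 mm) about the flexion axis with a
20 mm frontal radius, articulating on a biconcave insert with two toroidal
dishes (sagittal radius 45 mm, frontal 26 mm, 46 mm condyle spacing, 70 mm
width, 10 mm thickness). The articular radii are this package's own
choices, selected to give moderately conforming curved-insert contact of
realistic size; none are measured from a commercial implant. Constant
distal radius makes the flexion axis exactly the condylar centre, so
flexion produces pure sliding — the stated centre-of-rotation convention.
The coordinate frame is x anterior, y superior, z medial (left-knee,
right-handed); lengths mm, forces N, stresses MPa, work N·mm.

Consequences of the synthetic geometry are stated once and apply
throughout: absolute TKR predictions (wear rates, average contact area /
stress / CS per activity) are *not* comparable to the published per-implant
numbers, which required the proprietary geometry. What the package
guarantees instead is property-based: exact volumetric bookkeeping, force
balance at every solve, the closed-form Archard limit under forced constant
cross-shear, bounded basis-invariant cross-shear, and forward–inverse
recovery in the material-identification procedures.

## Activity profiles

`generate_profile()` builds 1 Hz waveforms whose extrema equal the printed
values exactly: peak loads 2600 / 2879 / 3008 N, peak AP translations
14 / 17 / 12 mm (anterior tibial shift negative, producing femoral
rollback), FE ranges 0–58 / 0–104 / 0–60°, IE ranges −5..5 / 0..5 / −5..5°
for walking, deep squat and stairs ascent. Only the extrema are
contractual; the shapes are raised-cosine stand-ins because the source
curves are not tabulated: double-peaked load for walking, single-peaked
otherwise, a 150 N swing-phase load floor (a typical simulator value), and
tibial rotation in quadrature with flexion, as in gait, so slip directions
rotate over the cycle and generate cross-shear. Extrema exactness relies on
the peaks landing on samples, hence `n_steps` must be a multiple of 4.
These synthetic waveforms under-generate cross-shear relative to measured
gait (cycle-average CS of order 0.005–0.02 versus the 0.03–0.06 reported
from measured kinematics), which is the main reason knee-loop wear rates
should be read comparatively, not absolutely. Users with measured (e.g.
ISO) profiles load them via the CSV schema
(`time_s, load_N, fe_deg, ap_mm, ie_deg`).

## The knee wear loop

One representative cycle is solved per update block in a two-pass scheme:
pass 1 solves the contact equilibrium at each of the `n_steps` poses
(128 by default) and accumulates, for every insert vertex, the tangential
sliding increments to the next pose and the frictional-work tensor; pass 2
assigns each vertex its whole-cycle cross-shear — the aggregation window is
one cycle, stated explicitly because the source defines wear per cycle from
nodal histories without fixing the window — and integrates
$\delta \mathrel{+}= \lvert ds\rvert \cdot C(CS_{\text{cycle}}, p/E)$ per
increment with midpoint pressures. Vertices with zero total frictional work
accrue zero wear. The nodal depths are scaled linearly over the update
interval (500,000 cycles by default), vertices recede along their inward
normals, and the next block re-solves on the worn surface; wear depths
remain far below the element size at these doses, so no re-meshing is
performed. Exhausting the insert thickness aborts the run. The load /
tibial-rotation axis is offset medially by 7 % of insert width per the ISO
recommendation; adduction–abduction is left unconstrained.

## Inverse material identification

Two displacement/load-controlled bench tests are inverted through
model-generated calibration curves (`calibration_curve()`, strictly
monotone, inversion by monotone interpolation, extrapolation refused):

* **Poisson's ratio** — cylinder compression (12 mm × 10.2 mm, 1 mm
  displacement). The forward model is a homogeneous-deformation
  end-expansion approximation, $A(\nu) = \pi (r_0 (1 + \nu\,\epsilon))^2$:
  displacement control makes the area independent of $E$, the area is
  strictly increasing in $\nu$, and $\nu = 0$ returns the nominal face
  area. A bonded-end model was considered and rejected: with fully bonded
  ends the face area would not depend on $\nu$ at all, contradicting the
  premise of the experiment; partial end slip is the physical regime, and
  the frictionless-limit kinematics is the simplest member of that family.
  No claim is made that this reproduces the published absolute value of
  0.32 — only the inverse-procedure mechanics (monotonicity,
  E-independence, round-trip recovery) are contractual.
* **Equivalent elastic modulus** — ball-on-flat at the 500 N peak of the
  zero-to-500 N sinusoidal load (the peak, not the mean, because the
  contact area was measured under dynamic loading and creep is absorbed
  into the "equivalent" modulus). The curve uses the Hertz-calibrated
  foundation backend and is strictly decreasing in $E$ with the Hertz
  $E^{-2/3}$ area scaling; forward–inverse round trips recover $E$ to
  better than 1 %.

## Fitting and validation conventions

`fit_coefficient_model()` fits the surface by nonlinear least squares
(Levenberg–Marquardt, non-negative bounds). The model has an exact scale
degeneracy $a\,(c, d) \leftrightarrow (\kappa a)(c/\kappa, d/\kappa)$, so
the scale $a$ is held fixed (default $1.47\times10^{-9}$) and only the
shape parameters $b, c, d, e$ are free; residuals are computed on $C/a$,
which keeps the optimiser well scaled. Initialisation is $b=100$, $c=1$,
$d=400$, $e=1.5$, with up to five jittered restarts under a fixed seed on
failure. Designs without variation in CS or in $P/E$ are rejected as
unidentifiable.

Agreement between predicted and measured wear rates is reported as the
**squared Pearson correlation**, not $1 - SS_{res}/SS_{tot}$. This is the
convention under which the bundled three-activity table (predicted 4.5 /
3.7 / 5.6, experimental 5.8 / 3.5 / 7.1 mm³ per million cycles) yields
0.94; the residual-based definition would give ≈0.40. The choice is
deliberate and surfaced here because the two conventions diverge strongly
for biased predictions.

## Numerical choices and degenerate inputs

* Vertex areas are the barycentric one-third split of incident face areas,
  so they partition the mesh area exactly (checked to 1e-9 relative).
* The rigid-envelope interpolation keeps only the branch below the centre
  of rotation (a flexed condyle folds over in x), uses an odd-count x grid
  so the midline is sampled exactly, and falls back to all rows for
  unfolded surfaces such as plates.
* Zero applied load short-circuits to the zero-pressure solution; zero
  total frictional work at a node is an error in `cross_shear()` but is
  treated as non-wearing by the cycle loop.
* Pin-face averaging uses an area-weighted polar grid (16 radii × 32
  sectors by default, stable to <2 % against refinement) plus an exact
  centre sample; both the face-averaged and centre-point CS are reported
  because the source does not say which one its matrix lists.
* CSV profile output is written at full double precision so round trips
  are bit-exact.

## Problem sizes

The shipped tests run the knee loop at grid resolution 24–32 with 16–32
steps per cycle and 1–4 × 10⁵-cycle blocks, and the contact benches at
grids 80–128 — sizes chosen so the whole suite completes in seconds while
every stated tolerance is met with margin. The defaults (grid 64, 128
steps, 500,000-cycle updates, multi-million-cycle doses) are the
documented long-running mode; scaling block counts is linear.

## Known limitations

* No creep or plastic deformation of the polyethylene — wear only; high-
  demand activities are therefore expected to be under-predicted.
* Counterface roughness effects are not modelled.
* The elastic foundation has no tangential (frictional) contact solution;
  friction enters only through the frictional-work bookkeeping.
* Synthetic geometry and synthetic waveform shapes: absolute knee-loop
  outputs are comparative, not implant-specific (see above).
```{r session}
sessionInfo()
```
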