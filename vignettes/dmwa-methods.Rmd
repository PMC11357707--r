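---
title: "Modeling directional microwave ablation in vertebral bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling directional microwave ablation in vertebral bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmwasim)
```

## The problem

Directional microwave ablation (dMWA) applicators concentrate dielectric
heating on one side of the shaft, which makes them attractive for
treating vertebral-body metastases: the tumor sits millimeters ventral of
the spinal cord, and an omnidirectional antenna would put the canal at
risk. Validating a treatment model in bone is harder than in liver-like
soft tissue — bone dielectric properties are roughly half (cancellous) to
a quarter (cortical) of soft-tissue values, their temperature dependence
is unreported, and the grossly visible ablation zone in bone does not
track the 55–60 °C isotherm the way it does in liver.

`dmwasim` is a desk-scale simulator for the ex vivo porcine
vertebral-body bench configuration used to validate such models: a
phantom of one vertebral body (cortical shell, cancellous core, dorsal
spinal canal, cranial/caudal disks) surrounded by air, a water-cooled
14-gauge directional applicator through the lateral wall, two fiber-optic
probes (T1 forward at 9.5 mm, T2 backward at 2.5 mm), and ablation
protocols of 40 or 60 W applied power (80/120 W generator setpoint after
the −2.84 dB cable budget) for 3.5 or 5 min at initial temperatures of
20, 30 or 37 °C.

## Governing model

Temperature obeys the bioheat equation without perfusion (ex vivo):

$$\rho c \,\partial_t T = \nabla\!\cdot\!(k \nabla T) + \rho\,\mathrm{SAR},$$

with static tissue properties. Bone's dielectric/thermal temperature
coefficients have not been measured, so no temperature feedback is
modeled; a hook for perfusion exists (`perfusion_coefficient`) but ships
disabled and is not used by any validation test. Boundary conditions are

* convective (Robin) exchange, $-k\,\partial_n T = h (T - T_\infty)$ with
  $h = 10\ \mathrm{W/m^2/^\circ C}$ and $T_\infty = 20$ °C, on every face
  between tissue and air — both the exposed vertebra/disk surface and the
  outer domain boundary;
* a fixed 30 °C (Dirichlet) temperature on the applicator surface,
  approximating the forced water cooling of the shaft;
* air is not treated as a conducting medium: it acts only through the
  convective condition and is reported at ambient temperature in the
  stored snapshots (at time zero the whole domain is reported at the
  initial temperature, matching the physical initial state).

## The directional source surrogate

The applicator's internal antenna geometry is proprietary, so a faithful
full-wave electromagnetic solution cannot be specified. The model of
record is a parametric directional line source — this is the central,
deliberate modeling choice of the package. The unnormalized deposited
power density at cylindrical coordinates $(r, \theta, x)$ about the shaft
(with $\theta$ measured from the radiation direction) is

$$q \propto D(\theta)\, e^{-x^2/2\sigma_a^2}\,
  \frac{e^{-2\int \alpha\, ds}}{\max(r, r_\mathrm{min})},\qquad
  D(\theta) = s + (1-s)\left(\tfrac{1+\cos\theta}{2}\right)^p ,$$

where $\alpha$ is the plane-wave attenuation constant of each traversed
tissue at 2.45 GHz (line integral by voxel ray marching, step =
spacing/2), $r_\mathrm{min}$ is the shaft radius (the 1/r spreading is
clamped there; power notionally inside the clamp is redistributed by the
global normalization), $\sigma_a$ is the axial Gaussian extent of the
active zone, $p$ the beam exponent, and $s$ the sidelobe floor. The
forward-to-backward density ratio at equal radius is $1/s$, so the
front-to-back ratio and sidelobe floor are one parameter; the constructor
derives $s = 1/\mathrm{FTB}$ unless overridden. 1/r (line-source) rather
than $1/r^2$ spreading reflects the elongated, shaft-parallel shape of
measured ablation zones. The field is scaled so deposited power equals
$\eta P_\mathrm{applied}$ exactly, with $\eta$ the absorbed fraction.

**Calibration.** The surrogate is anchored to one measured simulation
condition: the forward probe of the 80 W / 3.5 min / 20 °C protocol must
finish at 51.3 °C. Because the bioheat problem is linear and SAR is
proportional to $\eta$, the probe's final temperature is affine in
$\eta$; `calibrate_source()` therefore solves for $\eta$ exactly from two
runs, clamping to $\eta \in (0, 1]$, and only if that bound binds does it
fall back to a monotone root search over the sidelobe floor. The
procedure is deterministic. The calibrated $\eta \approx 0.082$ is much
smaller than the ~0.9 suggested by the sub-10% reflected power, and
should not be read as a reflection coefficient: it absorbs everything the
surrogate does not represent — above all that in the real applicator a
large share of the deposited power lands within the first millimeters of
the antenna and is immediately reclaimed by the chilled cooling water,
whereas the surrogate spreads that power over the phantom. The anchored
model then reproduces the remaining protocol conditions' forward
temperature changes to within 6–10% and the backward-channel ordering
(ΔT2 falling as the initial temperature rises 20 → 30 → 37 °C, because
the fixed 30 °C shaft removes proportionally more heat from the nearby
backward probe when the tissue starts warmer).

## Phantom and discretization choices

* **Coordinates**: x latero-lateral (shaft axis), +y ventral (radiation
  direction), z craniocaudal; origin at the default active-zone center.
  Voxel centers sit at `origin_corner + (i − 1/2)·spacing`.
* **Cross-section**: only bounding dimensions of the vertebral body are
  specified; the default is an elliptical prism (width × depth ellipse
  extruded craniocaudally, matching the rounded body shape), with a
  rectangular-box option. Volume checks carry tolerances that cover the
  shape choice.
* **Canal**: a straight 1.0-cm cylinder of spinal-cord tissue tangent to
  the dorsal body surface, running through the body+disk extent. Real
  canals widen toward mid-body; that non-uniformity is out of scope and
  is one reason externally referenced backward-probe distances (4.8 mm
  recorded) exceed the histology-derived 2.4 mm.
* **Probe distances are measured from the shaft axis**, not its surface
  (the convention is not fixed by the source measurements; the
  surface-referenced alternative adds the 1.055 mm shaft radius and is
  available by passing adjusted distances).
* **14-gauge** is taken as 2.11 mm outer diameter (standard gauge table).
* **Spatial scheme**: 7-point finite volume on the uniform voxel grid,
  harmonic-mean face conductivities across tissue interfaces (the
  original study used a 695k-element tetrahedral FEM; probe-level
  comparison does not need that mesh). Default spacing 1 mm; the
  1 mm / 10 s → 0.5 mm / 5 s refinement moves both probe temperatures by
  under 0.4%.
* **Time integration**: backward Euler with steps
  `duration/ceiling(duration/max_dt)` ≤ the 10 s maximum step;
  unconditional stability means no CFL constraint. Properties are static,
  so the system matrix is factored once (CHOLMOD) and reused.
* **Applicator coupling**: tissue voxels conduct into the fixed 30 °C
  shaft through a face conductance whose shaft side uses
  stainless-steel-like placeholder constants (k = 16 W/m/°C); since
  k_metal ≫ k_tissue the harmonic mean degenerates to the tissue-side
  half-cell resistance, i.e. the Dirichlet plane effectively sits at the
  voxel face.
* **Voxelization ties**: labels are assigned by voxel-center membership,
  which is deterministic. At 1 mm spacing the body/disk boundary plane
  (z = ±12.5 mm) passes exactly through voxel centers, so the thin disks
  carry a half-voxel bias at that spacing; convergence of class volume
  fractions is assessed between 0.5 and 0.25 mm where no boundary is
  center-aligned.

## Power chain

Cascaded passive losses add in dB: the five measured/estimated
components (−1.54, −0.17, −0.73, −0.20, −0.20) total −2.84 dB, i.e.
41.6 W reaches the antenna at the 80 W setpoint and 62.4 W at 120 W. The
protocol simulations use the nominal 40/60 W applied powers that drove
the reference simulations; the exact chain values are reported alongside
for transparency.

## Synthetic thermometry generator

`generate_batch()` emulates the ex vivo sensor logs so the comparison
pipeline is testable without measured data:

* radial placement distances drawn from truncated normals — mean 10.1 mm,
  bounds [8.3, 12.7] mm for T1; mean 2.4 mm, bounds [1.4, 3.6] mm for T2
  (histology-derived values; only means and ranges are known, so the
  normal family with sd = range/4 is this package's choice). The
  histology-derived 2.4 mm is the T2 default because it better represents
  true backward placement than the externally referenced 4.8 mm, which
  remains available as an alternate scenario;
* an axial out-of-plane offset ~ N(0, 1 mm);
* a per-replicate initial-temperature shift: warmed specimens cool from
  37 °C to ~N(30.2, 3.7²) °C during setup, room specimens sit at
  ~N(19.9, 0.8²) °C;
* additive i.i.d. N(0, 0.2²) °C sensor noise.

One private RNG stream per batch is seeded by a single integer; the
global RNG state is untouched. At n = 200 the replicate summaries recover
the placement mean within 0.3 mm and the warmed initial temperature
within two standard errors, and final T1 correlates negatively with
placement distance (farther forward = cooler), the direction the
placement-uncertainty argument requires. The generator does not simulate
sensor physics (response time, self-heating), tissue heterogeneity
within a class, or the true — unreconstructable — placement-error
distribution, so passing these tests says the pipeline's statistics are
correct, not that real placement errors are truncated-normal.

## Comparison statistics

`delta_T()` is final-minus-initial per channel; `percent_diff()` is
$100(\Delta T_\mathrm{sim} - \Delta T_\mathrm{exp})/\Delta T_\mathrm{exp}$
rounded half away from zero to an integer (this rounding reproduces all
six published signed percentages: forward −7/−5/−3%, backward
−11/−37/−33%). The reference tables embed two published quirks verbatim:
the forward experimental ΔT appears as 33.6 in the comparison table but
33.5 ± 2.9 in the replicate summary (the comparison takes its own columns
as given), and the backward-channel disagreement is quoted as 11–33% in
one place and 11–37% in another — the tabulated values, which contain
both −33 and −37, are treated as authoritative. Isotherm extents
(`ablation_extent()`) are measured on the final snapshot only — depth
along the radiation direction in the central cross-section, length along
the shaft, both with sub-voxel interpolation — and are deliberately not
compared against gross discoloration, which in bone does not track the
55–60 °C contour.

## Problem sizes

The validation suite runs the full pipeline at 1 mm spacing
(80×40×40 = 128,000 voxels, ~19,000 tissue unknowns, 21–30 implicit
steps), one refinement run at 0.5 mm (~1.02 M voxels), closed-form solver
checks on 8×8×8 to 60×7×7 blocks with an explicit 1 ms reference, and
n = 200 synthetic batches. These sizes were chosen so the whole analysis
reruns from scratch in minutes on one CPU while leaving the probe-level
quantities grid-converged to well under the tolerances being tested.

## Known limitations

* The angular pattern of the real antenna is unknown beyond its
  directionality; the surrogate cannot be validated beyond the probe
  temperatures and anchored conditions.
* Static properties: no dehydration, charring or temperature-dependent
  dielectric change; above ~100 °C the model ignores phase change, so
  uncalibrated (high-η) runs produce nonphysical peak temperatures.
* No thermal-damage integrals (Arrhenius/CEM43) — the validation data are
  isotherms and probe temperatures only.
* Ex vivo only: perfusion is off, and the air surround makes absolute
  temperatures higher than an in vivo, soft-tissue-embedded vertebra
  would reach.
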