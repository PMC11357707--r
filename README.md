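# dmwasim

Desk-scale simulation and validation pipeline for **directional microwave
ablation (dMWA) in vertebral bone**, built around the ex vivo porcine
vertebral-body bench configuration: a voxelized vertebra phantom
(cortical shell, cancellous core, spinal canal, intervertebral disks) in
air, a water-cooled 14-gauge directional applicator through the lateral
wall, and two fiber-optic thermometry probes — T1 forward (9.5 mm,
ventral) and T2 backward (2.5 mm, toward the canal).

The package is aimed at thermal-therapy modelers who want a transparent,
fully scriptable alternative to commercial FEM for probe-level questions:
how directional deposition, the −2.84 dB cable budget, the cooled-shaft
boundary and probe-placement uncertainty shape the measured temperatures.

## Model

Temperature follows the bioheat equation without perfusion (ex vivo),
with static tissue properties:

    rho c dT/dt = div(k grad T) + rho * SAR

solved by a 7-point finite-volume scheme on a uniform voxel grid
(harmonic-mean face conductivities) with backward-Euler steps ≤ 10 s,
convective exchange (h = 10 W/m²/°C, 20 °C) on all tissue–air faces, and
a fixed 30 °C on the cooled applicator surface. The microwave source is a
parametric directional line source,

    q ∝ D(theta) * exp(-x²/2σ²) * exp(-2 ∫ alpha ds) / max(r, r_min),
    D(theta) = s + (1-s) * ((1+cos theta)/2)^p,

with tissue plane-wave attenuation at 2.45 GHz along the radial ray,
normalized so deposited power equals `absorbed_fraction × applied_power`.
It stands in for the proprietary antenna's full-wave field and is
calibrated (exactly, via linear superposition) so the forward probe of
the 80 W / 3.5 min / 20 °C protocol finishes at the 51.3 °C anchor. See
`vignettes/dmwa-methods.Rmd` for the full account.

## Worked example

```r
library(dmwasim)

spec  <- phantom_spec()                      # 2.5 x 2.0 x 2.5 cm body, 2 mm cortex
pose  <- default_applicator_pose(spec)       # lateral entry, ventral radiation
prot  <- reference_protocols()[["P80_3.5min_20C"]]  # 40 W applied, 210 s, 20 C

sim <- make_anchor_simulator(spec, pose, prot, default_probes(pose)$T1)
cal <- calibrate_source(directional_source_params(), list(target = 51.3), sim)
run <- simulate_protocol(spec, pose, cal, prot)
delta_T(run$logs$T1); delta_T(run$logs$T2)
```

which prints (final/change in °C at each probe):

    $T_initial 20,  $T_final 51.3,  $delta 31.3     # T1, the calibration anchor
    $T_initial 20,  $T_final 32.95, $delta 12.95    # T2 (reference row: 33.4 / 13.4)

Rerunning the calibrated model over the remaining protocol conditions
gives forward temperature changes of 29.7, 28.6 and 57.5 °C against
reference values 32.5, 31.9 and 61.4 °C (within 6–10%), with the
backward channel's ΔT2 falling monotonically (12.9 → 6.7 → 2.2 °C) as
the initial temperature rises 20 → 30 → 37 °C — the cooled 30 °C shaft
removes proportionally more heat from the nearby backward probe in
warmer tissue. Feeding the published experimental and simulated ΔT
columns through `percent_diff()` reproduces the six printed signed
percentages exactly: −7, −5, −3% (T1) and −11, −37, −33% (T2).

The numbered drivers under `analysis/` run the same study as a
narrative: `01` phantom + power budget, `02` source calibration, `03`
protocol simulations and isotherm extents, `04` comparison tables, `05`
synthetic thermometry batches. Each writes its tables under `results/`.

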