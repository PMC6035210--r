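# btbimech

Mechanics toolkit for **primary blast-induced traumatic brain injury
(bTBI)** — the direct shock-wave loading of the brain during an explosion,
as distinct from fragment impact or acceleration-driven injury. It is
aimed at researchers in injury biomechanics and neurotrauma modelling who
want a desk-scale, fully scriptable counterpart to large 3-D explicit
finite-element head models: the same constitutive structure, injury
criteria and design questions, on 1-D layered columns that solve in
seconds.

## What is in the box

* **Constitutive models.** Finite-strain, near-incompressible
  viscoelasticity for grey matter (volumetric law *P = K(1 − J)* with
  pressure positive in compression, neo-Hookean equilibrium deviatoric
  stress on the distortional deformation *F\* = J^(−1/3) F*, one Maxwell
  branch for rate stiffening), and a transversely isotropic white-matter
  extension with a tension-only fibre term
  *σ\_f = (2 FA k\_f / J)(I₄ − 1) a\_t ⊗ a\_t* driven by the axonal
  direction and fractional anisotropy of diffusion-tensor data.
* **Injury criteria.** Pressure, von Mises stress, equivalent (Hencky)
  strain, volumetric and shear energy rates (stress powers), axonal
  stretch and axonal stretch energy rate — peak-value criteria with
  calibrated damage thresholds of **100 MJ/m³s** (shear energy rate,
  grey matter) and **1.5 MJ/m³s** (axonal stretch energy rate, white
  matter).
* **Fibre extraction.** Principal eigenvector and FA of voxel diffusion
  tensors, nearest-voxel mapping onto material points.
* **Blast loading.** Kinney–Graham free-air scaled-distance peak
  overpressure, Friedlander waveforms, and the two study presets
  (2.3 kg C-4 at 2.3 m → 360 kPa; 3 kg Octol at 2 m → 1.3 MPa).
* **Wave solver.** Explicit 1-D Lagrangian solver (planar or spherically
  symmetric) for layered shield/skin/skull/CSF/brain/ventricle columns,
  with artificial-viscosity shock capture, energy-conservation
  diagnostics, and direct export of per-point deformation/stress
  histories to the criteria module.
* **Shield design.** The two-region protective-shield trade study:
  damage maps over acoustic-impedance ratio √(E₂ρ₂)/√(E₁ρ₁) and
  wave-speed ratio √(E₂/ρ₂)/√(E₁/ρ₁) relative to a polycarbonate centre
  region, plus a material-selection overlay.
* **Region scoring.** The 6 × 9 forebrain region grid (53 labelled
  regions, 8 oxidative-stress-damaged) and the matching-accuracy score
  between predicted and observed damaged regions.

## Worked example

```r
library(btbimech)

# 1. A blast scenario and its free-field peak overpressure
sc <- blast_scenario(2.3, "C4", 2.3)
sc
#> <blast_scenario> 2.3 kg C4 (TNT eq. 1.2) at 2.3 m standoff
#>   scaled distance Z = 1.64 m/kg^(1/3), peak overpressure ~ 330.4 kPa
```

The scaled-distance fit gives 330 kPa for this scenario, within 10% of
the 360 kPa magnitude reported for it.

```r
# 2. Injury criteria at a material point under fast simple shear
h <- make_deformation_history("simple_shear", rate = 1000,
                              amplitude = 0.2, duration = 4e-4, dt = 5e-6)
evaluate_point(h, grey_stress(h), criteria = default_criteria("grey"))
#>                criterion      peak  t_peak threshold exceeded
#> 1               pressure 1.480e-13 9.5e-05       Inf    FALSE
#> 2              von_mises 1.096e+03 2.0e-04       Inf    FALSE
#> 3      equivalent_strain 1.153e-01 2.0e-04       Inf    FALSE
#> 4 volumetric_energy_rate 0.000e+00 0.0e+00       Inf    FALSE
#> 5      shear_energy_rate 6.323e+05 2.0e-04     1e+08    FALSE
```

Shear at 1000/s to 20% strain produces a peak shear power of
0.63 MJ/m³s — two orders of magnitude below the 100 MJ/m³s grey-matter
damage threshold (the pressure row is ~0 because simple shear is
isochoric).

```r
# 3. Blast on a spherically symmetric human head column
fh <- solve_column(make_toy_head("human_like"),
                   scenario_presets("c4_low")$profile,
                   solver_config(2e-4))
fh
#> <field_history> spherical column, 206 elements, 995 frames, dt = 2.01e-07 s
#>   peak |axial stress| = 6.842e+06 Pa
#>   energy closure at end: 0.112% of external work
damaged_fraction(fh)
#> [1] 0
```

The low-intensity scenario does not breach the shear-energy-rate
threshold anywhere in the brain layer — consistent with the expectation
that ~360 kPa exposures sit below the primary-blast injury range (the
caveats of the 1-D surrogate are discussed in the vignette).

```r
# 4. Scoring a prediction against the experimental region labels
labs <- load_experimental_labels()
pred <- data.frame(region = labs$region,
                   predicted = labs$status == "damaged")
pred$predicted[labs$region %in% c("A4", "B5")] <-
  !pred$predicted[labs$region %in% c("A4", "B5")]  # two deliberate errors
matching_accuracy(pred, labs)
#> [1] 96.22642
```

Two misclassified regions out of 53 labelled gives 96.2% matching
accuracy.

The shield trade study runs as
`sw <- shield_sweep()` (≈ 82 column solves, about half a minute) and
returns per-cell damaged fractions and peak shear-power exposure;
`sweep_matrix(sw)` lays the map out with impedance ratios as rows and
`material_selection_map()` overlays candidate materials.

## Layout

```
R/                 constitutive, criteria, fibers, blast, wave_solver,
                   shield, regions, fixtures, io
inst/extdata/      region label fixture (partly synthetic; see vignette)
inst/cli/btbi.R    command-line wrapper
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette: models, assumptions, limitations
scripts/           acceptance script
```
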