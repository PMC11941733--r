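# aortafem

Finite-element wall stress and rupture-risk assessment for abdominal aortic
aneurysms (AAA), as a fully scripted, testable R pipeline.

## The problem

An abdominal aortic aneurysm is a focal dilation of the abdominal aorta to
more than 150% of its normal diameter. Clinical management hinges on
estimating the risk that the weakened wall ruptures under pulsatile blood
pressure. Patient-specific finite-element analysis (FEA) of the aortic wall
is increasingly used for this: segment the lumen from CT, build a wall
model, load it with blood pressure, and read off where stresses, strains and
displacements concentrate. `aortafem` re-implements that workflow end to end
for researchers in vascular biomechanics who need a transparent, scriptable,
dependency-light reference pipeline — with a synthetic-anatomy generator in
place of private patient CTs, so every stage is reproducible and testable.

## What it computes

* **Synthetic anatomy** — fusiform aneurysm lumens with a Gaussian bulge
  radius profile r(z) = r_neck + (r_max − r_neck)·exp(−((z − z_c)/w)²),
  diagnostic diameters 2·r_max in the 48–68 mm cohort range, and noisy voxel
  phantoms standing in for contrast CT.
* **Reconstruction** — threshold segmentation, largest connected component,
  marching-tetrahedra isosurface extraction at level 0.5, Taubin
  (shrink-compensated λ/μ) smoothing.
* **Wall meshing** — outward extrusion of the lumen surface along
  area-weighted vertex normals into a conforming tetrahedral wall mesh
  (uniform thickness, default 2 mm) with tagged inlet/outlet node sets and
  lumen faces.
* **Elastostatics** — linear isotropic material (E = 0.7 MPa, ν = 0.45,
  ρ = 1095 kg/m³), constant-strain tetrahedra, sparse Cholesky solve; lumen
  pressure as a dead load on the reference geometry, inlet and outlet fully
  fixed; pulse pressure ramped in 10 increments from ΔP = 50 mmHg to the
  final ΔP = 77 mmHg.
* **Post-processing** — per-element von Mises stress
  σ_vm = √(½[(σ₁₁−σ₂₂)² + (σ₂₂−σ₃₃)² + (σ₃₃−σ₁₁)²] + 3(σ₁₂²+σ₂₃²+σ₃₁²)),
  equivalent (von Mises) strain ε_eq = √(⅔ ε_dev:ε_dev), maximum nodal
  displacement, and the systolic diameter D_sys = D_dias + max‖u‖.
* **Rupture risk** — the pressure–strain modulus
  P_psm = D_dias·(P_sys − P_dias)/(D_sys − D_dias) (kPa), mapped through a
  saturating risk curve risk = 1 − exp(−k·P_psm) calibrated by least squares
  on a packaged 12-case reference cohort (k ≈ 0.017 kPa⁻¹, max residual
  < 0.01 percentage points).

## Worked example

```r
library(aortafem)

spec <- anatomy_spec(neck_radius = 11, max_radius = 25.5, bulge_center = 60,
                     bulge_width = 20, total_length = 120, wall_thickness = 2)
surf <- generate_lumen_surface(spec, n_circumferential = 48, n_axial = 72)
mesh <- tag_boundaries(extrude_wall(surf, spec$wall_thickness, n_layers = 2), surf)
sol  <- solve_static(mesh, material_model(), load_case())
res  <- field_result(mesh, material_model(), sol)
res
#> field_result (dP = 77.0 mmHg): max von Mises 0.1103 MPa, max eq. strain 15.2%, max |u| 2.80 mm

rec <- case_summary(res, 2 * spec$max_radius, "example", mesh)
tab <- risk_calibration_table()
curve <- calibrate_risk_curve(data.frame(ppsm_kpa = tab$ppsm_kpa,
                                         risk = tab$risk_percent / 100))
curve
#> risk_curve: risk = 1 - exp(-k * Ppsm), k = 0.016999 /kPa (fit on 12 pairs, max resid 3.74e-05)
risk_report(list(rec), load_case(), curve)
#>   case_id diagnostic_diameter_mm systolic_diameter_mm ppsm_kpa risk_percent
#> 1 example                     51                 53.8    187.1        95.84
```

Reading: a 51 mm aneurysm with an assumed 0.7 MPa wall dilates by 2.8 mm
under a 77 mmHg pulse; that small pulsatile dilation means a *stiff* wall,
hence a high pressure–strain modulus (187 kPa) and a rupture-risk estimate
of 95.8% on the calibrated curve. (Stiffness-based risk rises as dilation
*shrinks* — see the methods vignette for the interpretation caveats.)

The same run, end to end with artifacts and manifests on disk:

```r
run_stage("all", pipeline_config(n_cases = 12, seed = 1, output_dir = "run"))
```

or from the shell:

```sh
Rscript inst/cli/aortafem_cli.R all --out run --seed 1 --n-cases 12
```

## Layout

* `R/` — implementation (anatomy, reconstruction, meshing, FEM, post,
  risk, pipeline, I/O: STL/VTU/raw-volume/JSON).
* `inst/extdata/` — packaged calibration cohort (CSV).
* `inst/cli/aortafem_cli.R` — command-line front end.
* `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code).
* `vignettes/aortafem-methods.Rmd` — the model, its assumptions, numerical
  choices and known limitations.
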