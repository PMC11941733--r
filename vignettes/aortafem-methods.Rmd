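---
title: "aortafem: models, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aortafem: models, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortafem)
```

This vignette is the package's own account of its science: what is modelled,
which knobs matter, what the synthetic data does and does not emulate, and
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The structural model

The aortic wall is treated as a homogeneous, isotropic, linearly elastic
solid of uniform thickness, loaded statically by a spatially uniform lumen
pressure and fixed (all displacement components zero) on the inlet and
outlet cross-sections. This is the deliberately simple end of AAA
biomechanics — no hyperelasticity, no anisotropy or layering, no thrombus
or calcification, no fluid–structure interaction, no zero-pressure-geometry
recovery — chosen for speed and auditability in rapid-screening settings.

Material defaults (exposed in `material_model()`):

| parameter | default | unit | why |
|---|---|---|---|
| Young's modulus E | 0.7 | MPa | conventional aortic-wall screening value |
| Poisson ratio ν | 0.45 | – | near-incompressible soft tissue; ν = 0.5 unsupported (incompressible limit) |
| density ρ | 1095 | kg/m³ | carried for completeness; unused in statics |

Loading (`load_case()`): pulse pressure ramped in `n_steps = 10` increments
from ΔP = 50 mmHg (the low 130/80 pair) to ΔP = 77 mmHg. The quoted
high-pressure pair is 230/123 mmHg, whose arithmetic difference is 107, not
77 mmHg; the workflow this package mirrors *states* 77, so 77 is the
default and the field is exposed so either convention can be run. With a
linear model each increment is an exact proportional rescaling of the final
solve — the stepping is retained for interface parity with nonlinear
solvers, and the proportionality is itself a regression test.

Unit policy: geometry in mm and pressures in mmHg at every user-facing
boundary; the assembler and solver work in SI (m, Pa, N). The mmHg→Pa
factor is fixed at 133.322.

### Elements and solver

Constant-strain (linear) tetrahedra. The element stiffness uses the
closed-form isotropic block expression K[3a+i,3b+j] = V(λ g_aᵢ g_bⱼ +
μ g_aⱼ g_bᵢ + μ δᵢⱼ g_a·g_b); it is verified in the tests against a 12×12
reference-tet matrix computed once in exact rational arithmetic. The global
system is solved by sparse Cholesky factorisation (Matrix package) on the
free DOFs; one factorisation serves all load increments. CST elements are
exact for affine displacement fields (the patch test asserts this to
1e-10) and converge on the thick-walled-cylinder benchmark: inner-wall hoop
stress within 2% of the Lamé solution at ν = 0.3, and within 5% with a
decreasing error trend at ν = 0.45, where mild volumetric locking slows
convergence. The Lamé benchmark uses axial-only end constraints (exact
plane strain) rather than a very long fully-fixed tube — same physics,
desk-scale cost — and compares element-centroid stresses against the
closed form evaluated at the centroid radius, which isolates discretisation
error from evaluation-point offset.

### Pressure load

Each lumen triangle contributes p·A/3 to its three nodes along the
direction from lumen into wall, using reference-configuration normals (dead
load). This matches the small-deformation assumption; it also means the
computed 15–20% peak strains are, strictly, outside the regime where that
assumption is quantitative. The reference workflow reports strains of
35–80% under the same linear treatment; the package reproduces the linear
treatment and flags the inconsistency rather than resolving it.

## 2. Synthetic anatomy: a stated world

No patient CTs are distributed, so every downstream stage is exercised on
parametric fusiform aneurysms:

* radius profile: Gaussian bulge over a straight neck. The bulge law is a
  package choice (no shape law is published for the cohort); it is smooth
  and decouples aneurysm length (`bulge_width`) from diameter.
* diagnostic diameters uniform on [48, 68] mm — the printed cohort range;
  neck diameter 20–24 mm, segment length 110–130 mm, bulge width 18–25 mm,
  mild asymmetry (0–0.3): conventional adult AAA proportions, chosen once.
* wall: uniform 2 mm. Thickness is an acknowledged unknown in this problem
  class; 2 mm is the conventional literature value and is exposed per-spec.
* phantoms: intensity 1 inside the lumen, 0 outside, plus seeded Gaussian
  noise (default sd 0.1 = 10% of contrast) emulating the fluid noise of
  contrast CT. Deterministic given (spec, voxel size, noise sd, seed).

What the generator does **not** emulate: Hounsfield calibration, organ
background, partial-volume effects, iliac bifurcation, saccular shapes,
thrombus. A green reconstruction test therefore establishes that the
segmentation→surface→smoothing chain is geometrically faithful on clean
tubular anatomy with additive noise — not that it would segment a real CT.

## 3. Reconstruction: numerical choices

* **Threshold** at 0.5 (half contrast), closed interval; with 10% noise the
  misclassification probability per voxel is the 5σ tail, effectively zero.
* **Largest component** under 26-connectivity (the usual choice in medical
  segmentation); ties broken toward the lowest-linear-index seed so the
  operation is deterministic.
* **Isosurface**: marching *tetrahedra* on the Kuhn (six-tet) subdivision of
  each voxel cell, at level 0.5. Marching tetrahedra was chosen over
  table-driven marching cubes because it is derivable from first principles
  (no 256-case lookup table to import), inherently watertight, and
  vectorisable in R. A raw binary indicator field yields stair-cased
  surfaces whose area overestimates smooth anatomy by tens of percent —
  with *any* midpoint-interpolating isosurfacer — so `extract_surface()`
  first applies one separable [¼, ½, ¼] smoothing pass to the indicator;
  measured on a voxelised 15 mm ball at 1 mm spacing this brings the area
  error from ≈ +29% to ≈ +1.6% and volume error under 1%. The pass is
  disabled with `presmooth = FALSE` (needed to preserve single-voxel
  features, whose smoothed field never crosses the 0.5 level).
* **Smoothing**: Taubin λ/μ (0.5 / −0.53, exposed), uniform weights,
  boundary loops pinned. Chosen over plain Laplacian smoothing because it
  does not shrink: 100 iterations change a sphere's volume by under 1%,
  which keeps reconstructed diameters unbiased — the property the
  downstream diameter-based risk index depends on.
* **Diameter measurement**: per-slab maximum chord computed on the 2D convex
  hull. An earlier centroid-based measure was biased by up to 10% because
  the Kuhn subdivision's vertex density is direction-dependent; the max
  chord is density-invariant.

## 4. Wall meshing

The lumen surface is offset outward along area-weighted vertex normals in
`n_layers` equal shells (default 2 through the 2 mm wall, ≈1 mm elements);
each prism splits into three tets by a smallest-global-index diagonal rule,
which makes diagonal choices agree across neighbouring prisms, so the mesh
is conforming by construction (asserted: every interior face shared by
exactly two tets). Offsets exceeding the local curvature radius invert
elements; this is detected and reported with the offending vertices rather
than returned. A structured extrusion was preferred to an unstructured
Delaunay mesher: deterministic, dependency-free, and sufficient for tube
topology; externally meshed VTU/text meshes can be imported instead.

Inlet/outlet sets are all through-thickness copies of the two boundary
loops; whether the reference workflow fixed all components or only normal
ones is unstated — full fixation is implemented, matching "fixed surfaces"
literally. Solid tets rather than shells are used throughout; the reference
images suggest shell-like post-processing, but the stated 1 mm tet sizing
commits this implementation to solids, and the choice is recorded here.

## 5. Rupture risk

The pressure–strain modulus P_psm = D_dias(P_sys − P_dias)/(D_sys − D_dias)
is evaluated in kPa. The risk mapping is *not* hard-coded: the packaged
12-case table (systolic diameter, P_psm, risk %) is fitted at run time by
least squares over the single rate parameter of risk = 1 − exp(−k·P_psm),
and the fit residual is stored on the curve object. Model selection is kept
as a build oracle in the test suite: the exponential form reproduces all 12
printed risks to within 0.01 percentage points (and each row under
leave-one-out calibration to 0.05 pp), whereas the best two-parameter
hyperbola P/(P+c) misses by whole percentage points. Two documented
inconsistencies in the source material are reported, not resolved:

* no single ΔP reproduces the printed P_psm values from the printed
  diameters (the printed P_psm values are therefore treated as
  authoritative inputs for calibration);
* the claim that 200 kPa implies > 98% risk conflicts with the calibrated
  curve, which gives ≈ 96.6% at 200 kPa; `risk_report()` carries the
  annotation.

Interpretation caveat: by Eq.-level algebra, *stiffer* walls (smaller
pulsatile dilation) score higher P_psm and thus higher risk; the
cohort-level claim "larger aneurysm, higher risk" is an empirical statement
about the reference cases, not an algebraic consequence. The package
reports both diameters and the index so users can audit the direction.

The systolic diameter uses the dominant printed bookkeeping
D_sys = D_dias + max‖u‖, which reproduces 8 of the 12 reference rows
exactly; the four exceptions follow no recoverable rule, so a
cross-section-based alternative (max chord of the deformed lumen) is
reported side by side and neither is forced.

## 6. What the tests establish — and don't

The suite validates geometry against closed forms (cylinder area, sphere
area/volume, shell volume, Lamé), the FE core against exact oracles (symbolic
element matrix, patch test, equilibrium, proportionality, permutation
invariance), reconstruction fidelity on phantoms (volume within 3%, diameter
within 2%, noise ≤ 10%, seeds 0–4), and the risk calibration against the
packaged table at the printed precision. The 12-case synthetic cohort lands
its maximum von Mises stresses at O(0.1) MPa — the right order of magnitude
but below the 0.25–0.7 MPa printed for patient anatomy, as expected: smooth
idealised fusiform shapes concentrate stress less than real lumpy aneurysms,
and the per-patient values are not reproducible without the patient CTs.
That corridor is reported, not asserted as a hard bound. Default test-suite
mesh sizes are deliberately desk-scale (tens of thousands of elements);
1 mm sizing on a full cohort geometry reaches the 10⁵-element class the
reference workflow quotes, at proportionally higher runtime.

## 7. Known limitations

Linear kinematics at double-digit strains; dead pressure loads; uniform
wall thickness; single unbranched tube; no prestress; risk curve calibrated
on 12 cases of one cohort and valid only on its P_psm scale (kPa); the
reconstruction path assumes two-level contrast. These bounds are inherited
from the modelling regime the package deliberately reproduces.
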