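---
title: "Artificial vertebral-segment models and the distortion-energy response angle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artificial vertebral-segment models and the distortion-energy response angle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertefem)
```

## Scope and model

`vertefem` analyses the mechanical state of a scoliotic apex segment with a
deliberately idealised geometry.  Instead of segmenting CT images, each
vertebral body is an *artificial geometric solid* determined by a small
parameter set: height, lower/upper face radii, four wedge angles (top and
bottom faces, coronal and sagittal planes) and two rigid tilts.  The
segment model is five solids — lower neighbour, lower disc, apex, upper
disc, upper neighbour — with planar disc–vertebra interfaces.

This idealisation is a feature, not a shortcut: local surface roughness of
segmentation meshes dominates pointwise stress read-outs, while the wedge
and tilt of the bodies are exactly the deformity features the analysis is
about.  The model is therefore appropriate for semi-global questions
(where on the apex face does the deviatoric energy concentrate, and at
what angle relative to the pelvis frame) and inappropriate wherever local
surface detail is the quantity of interest.

All geometry lives in the scanner-bed frame: **+z** axial/up (the stacking
direction), **+x** patient-left, **+y** anterior.  Angles printed by the
package are degrees; lengths are mm; stresses, moduli and energy densities
are MPa (1 MPa = 1 MJ/m³).

### Construction stages

1. *Rotation solid.*  `build_rotation_solid(h, r1, r2)` is the frustum
   obtained by revolving the coronal trapezoid about its vertical side.
   A degenerate cone (`r2 = 0`) is rejected.
2. *Wedge cuts.*  `apply_wedge()` re-cuts a face with a plane rotated by
   the wedge angle about a hinge through the face edge, on the side where
   the body heights coincide — so cuts only remove material, and repeating
   a cut is idempotent.  Positive coronal angles thin the body towards
   patient-right, leaving it thicker on the (convex) left; positive
   sagittal angles thin it posteriorly, so an apical lordosis is a
   negative sagittal wedge.  After several cuts a face is the min/max of
   its cut planes; each cut face is meshed exactly planar, so the imposed
   dihedral angle is recovered from the mesh to machine precision.
3. *Tilt.*  `apply_tilt()` rotates rigidly about x then y, pivoting on the
   solid centroid; volume is preserved exactly.  The construction order
   and pivot are conventions of this package (any two axes suffice for a
   3-D rotation, and no pivot is canonical); they are documented because
   the orthotropic material frame follows the same rotation.
4. *Assembly.*  `assemble_spine()` stacks the three bodies along +z with
   the prescribed disc gaps and lofts each disc linearly between the
   adjacent vertebral faces.  The disc shape is this package's choice (a
   linear loft whose lateral radius follows the interpolated face radii);
   nothing finer is warranted by the disc's role here.

### Meshing

All solids are swept bodies over one shared triangulated disc
cross-section, extruded layer by layer; each prism is split into three
tetrahedra.  Two properties are engineered in:

* *Conforming interfaces.*  Disc meshes reuse the vertebral face nodes
  verbatim, so disc–vertebra interfaces share nodes exactly — no gluing
  tolerance exists anywhere in the mesh.
* *Exact mirror symmetry.*  The cross-section carries 8k nodes on ring k,
  the triangulation is built on one quarter and replicated by the axis
  reflections, and prism diagonals are chosen by a reflection-invariant
  node priority (ring, distance to axis, angle).  Mirroring a patient's
  parameters across the sagittal plane then yields the exact mirror mesh
  (node sets agree to ~1e-14), which is what makes the end-to-end mirror
  equivariance of the response angle testable at numerical precision
  rather than at mesh-asymmetry level (raw-index diagonal selection left
  4–20° of spurious asymmetry in the response angle).

The characteristic edge length defaults to `min(r_lower)/5` (~3 mm for
thoracic bodies), giving ~2·10⁴ tetrahedra per segment; `size` and
`n_rings` are exposed.  The lateral surface of a swept wedged frustum
deviates from the exact Boolean cut by O(wedge slope × radius taper) —
irrelevant at the wedge angles of interest (≤ ~12°) and invisible to the
planar faces, which are exact.

## Materials

Voigt order is fixed package-wide to (xx, yy, zz, yz, xz, xy) with
engineering shear strains; with that convention the stiffness matrix maps
strain to stress without extra factors (the classical ½ factors of the
tensorial-to-engineering map are absorbed into the strain vector).
Defaults (overridable via YAML, `inst/extdata/materials.yaml`):

| phase | model | constants |
|---|---|---|
| bone | isotropic | E = 3500 MPa, ν = 0.25, ρ ≈ 1908 kg/m³ |
| bone | orthotropic | Y = (11300, 11300, 22000) MPa; G = (3800, 5400, 5400) MPa as (G_xy, G_yz, G_xz); ν = (0.484, 0.203, 0.203) as (ν_xy, ν_yz, ν_zx) |
| disc | isotropic | E ≈ 252 MPa, ν ≈ 0.47, ρ ≈ 1120 kg/m³ |

The orthotropic stiffness is assembled as the inverse of the engineering
compliance (reciprocal Poisson relations implied); symmetry and positive
definiteness are checked, and a violation names the condition.  The disc
is always isotropic.  The listed disc modulus is far stiffer than typical
annulus measurements (~2–8 MPa); it is nevertheless the shipped default — it is
the constant the segment model's reference analysis was calibrated with —
and it is a one-line YAML override for users who prefer physiological
values.
Density enters only if self-weight loading is added by the user; the
fifteen load-states use boundary tractions only.

`rotate_stiffness()` applies the vertebral tilt to the 4th-order tensor
(C'ᵢⱼₖₗ = R·R·R·R·C); `stiffness_spectrum()` returns the Kelvin (Mandel)
eigenvalues, which are the representation-independent tensor invariants —
note that the raw eigenvalues of the engineering-Voigt matrix are *not*
rotation-invariant, a point that matters when validating rotations.

## The elastic solve

Linear (P1) tetrahedra, element-wise constant strain and stress; assembly
is vectorised over elements per material domain; the bottom face of the
lowest vertebra is fully constrained; tractions are constant per patch and
distributed to patch-triangle nodes by area thirds.  The reduced system is
solved by sparse Cholesky (Matrix), and the factor is reused across all
load-states of one model — the fifteen states differ only in their
right-hand sides.  Residuals are reported per solution (~1e-12 relative in
practice; anything above 1e-8 should be treated as a failure).

The distortion-energy density is the deviatoric strain-energy density
U_d = ½ s_dev : e_dev, which for isotropic materials equals the von-Mises
form (1+ν)σ_vM²/(3E) and extends consistently to orthotropy.  Where the
two candidate orthotropic generalisations (deviatoric product vs von-Mises
form with isotropic constants) differ, the deviatoric product is used: it
is the energy actually stored in shape change for the material at hand.

*Stress recovery.*  Stress is element-wise (exact for constant-strain
elements), but the field handed to the response-variable extraction is the
volume-weighted **nodal average** interpolated linearly over the apex top
plane.  Element-constant energy fields carry O(h) jumps; the focus-point
rule thresholds the field within 2 % of its maximum, and on raw
element-constant fields the membership of that near-maximal set is
knife-edge unstable (mirror-image models disagreed by up to 20° in the
response angle).  Nodal averaging is the standard smoothing recovery and
restores stability without touching the solve.

## Load-states and the response variable

`enumerate_load_states()` returns the fifteen states: LS1–LS4 press one
sacrum-aligned quadrant of the top face with 1 MPa in −z, LS5 presses all
four, each also emitted with clockwise / counter-clockwise tangential
tractions (default 0.5 MPa) on two circular lateral patches of the upper
vertebra.  Quadrants are labelled in the sacrum-aligned frame: q1
anterior-left, q2 anterior-right, q3 posterior-right, q4 posterior-left.
The quadrant split lines pass through the top-face centroid, one parallel
to the sacrum line (the "horizontal"), one perpendicular; the partition is
exact by construction (each top-face triangle goes to exactly one
quadrant by centroid position), so quadrant areas conserve the face area
to rounding.  The shear patches are centred at ±x on the lateral surface
at a height fraction (default 0.5) with default radius 0.35 × body height;
both are exposed parameters, since no canonical placement exists.

On the apex top plane, `sample_apex_plane()` lays the interpolated energy
field on a regular grid (default 41×41) over the section, with the
section's area centroid as origin and the projected sacrum line ℓ as
reference direction.  `focus_point()` implements the response-variable
definition with three discretisation constants: the plateau tolerance
(2 % of the maximum), the subdomain cutoff (4 grid cells — anything
smaller is treated as a maximal *curve or point* and represented by the
argmax location), and the area tie tolerance (5 %, ties averaged).  All
candidate components are reported with areas and centroids, so an
investigator can override the deterministic rule instead of the ad-hoc
manual choice the original workflow allowed.

`apex_top_response_angle()` returns the signed angle (counter-clockwise
positive viewed from +z) between ℓ and the centroid-to-focus line,
**reduced to (−90°, 90°]**.  Both references are lines, not rays: the
sacrum line has no intrinsic orientation (the package orients its
direction vector towards +x purely for computation).  On the full
(−180°, 180°] range the angle would jump by 180° depending on that
orientation convention and would transform as θ → 180° − θ under sagittal
mirroring; on the line-to-line range it is continuous in the data and
mirroring negates it exactly, which is also the invariant the test-suite
checks end-to-end.

## Landmark measurements

`apex_rotation()` is the Aaro–Dahlborn-variant axial rotation: the
unsigned angle at the neural groove between the body-symmetry line and
the groove-to-sternum line, after projection to the measurement plane.
The symmetry line is supplied as two points — the "roughly symmetric with
respect to mass" choice is observer-dependent and out of scope — but
`symmetry_bisector_check()` implements the a-posteriori check: a circle
about the groove should meet the canal boundary in two points whose angle
bisector coincides with the chosen line; the returned deviation is 0 for
a perfectly symmetric choice.  `sacrum_table_angle()` implements the
five-step pelvis measurement on coordinates and returns the angle of the
axially-projected sacroiliac line to the bed x-axis, positive clockwise
viewed from above, together with the sacrum line direction used as ℓ.

## Synthetic cohort

`generate_cohort()` emulates the structure of a five-patient right-convex
idiopathic thoracic cohort.  Severity enters the geometry through one
explicit stand-in: the apex coronal wedge is `0.2° per degree` of apex
rotation (split equally between the apex faces; neighbours carry half the
apex wedge and lean into the curve), plus optional truncated Gaussian
noise.  The apical lordosis is a fixed −5° sagittal wedge.  Default apex
rotations (33, 9.7, 49.9, 22.9, 40.5)° and sacrum angles (−1.5, 7.3, 0.4,
2.1, 2.7)° are the reference cohort's values (`reference_cohort()` carries
the full metadata); heights 18–22 mm, radii 12–15 mm and disc gaps 4–6 mm
are ordinary mid-thoracic adolescent dimensions.  Generation is
deterministic given the spec seed.

What this emulates: a monotone rotation–wedge relationship with
controllable noise, right-convex orientation (thicker on patient-left,
+x), slight apical lordosis, plausible body proportions.  What it does
not: real endplate curvature, posterior elements, rotation-dependent
axial geometry (the pre-wedge body is axisymmetric, so axial rotation per
se has no geometric effect), inter-patient correlation structure, or any
imaging noise.  Green pipeline tests therefore demonstrate that the
machinery is correct and internally consistent — not that the synthetic
correlations transfer to patients; the cohort statistics of a synthetic
run characterise the generator, nothing more.

## Cohort statistics

`sample_correlation()` is the Pearson product-moment correlation between
the per-patient apex rotations and response angles of one load-state
(delegated to `stats::cor`; the test suite checks it against an
independent two-pass evaluation of the defining summations).
`paired_ttest()` is the two-sided paired t-test on y − x
(`stats::t.test`; checked against an incomplete-beta t-CDF oracle to
1e-9).  `run_cohort()` assembles the study design: five correlations
(isotropic, shear-free states), four paired comparisons — basic vs +cw
shear, basic vs +ccw shear, ccw vs cw, isotropic vs orthotropic — each
over the 25 patient × basic-state pairs in patient-major, load-state-minor
order, and the load-state of maximal |ρ|.

## Numerical choices and degenerate inputs

* Wedge angles outside (−45°, 45°), non-positive radii/heights/gaps and
  ν ≥ 0.5 are rejected with typed error messages
  (`vertefem_parameter_error`, `vertefem_geometry_error`,
  `vertefem_consistency_error`, ...); cuts that consume the solid and
  assemblies whose tilted bodies overlap raise geometry errors naming the
  offending interface.
* Constant planar fields raise a non-constancy error (the focus point is
  undefined); a focus point within one grid cell of the centroid raises
  an undefined-angle error rather than returning a noise-dominated angle.
* All geometry tolerances (plane fits, watertightness checks in tests)
  are relative to the bounding-box scale; the solver reports its residual
  rather than asserting it silently.

## Problem sizes

The shipped tests and the acceptance script run the full design — five
patients × two material models × fifteen load-states — at the default
~3 mm mesh (~2·10⁴ tetrahedra, ~2·10⁴ degrees of freedom per patient),
which the package solves in about a minute on one CPU because each
patient–material pair is one factorisation plus fifteen forward solves.
The uniaxial benchmark uses a 20 × ⌀30 mm cylinder at two refinements;
the convergence test tracks external work over three refinements.  These
sizes are the package's reference configuration; everything scales with
`size`/`n_rings` for users who need finer fields.

## Known limitations

* Vertebral bodies only: no posterior elements, ligaments, nucleus/annulus
  substructure or endplates; shear is applied on lateral body patches.
* Small-strain linear elasticity: no contact, geometric nonlinearity,
  time dependence or growth modelling.
* The response variable needs a clear energy concentration; for nearly
  symmetric models under LS5 the focus point approaches the centroid and
  the angle is (correctly) reported as undefined.
* The artificial geometry is axisymmetric before wedging, so patient
  axial rotation must be carried by the wedge/tilt mapping — a modelling
  choice made explicit in the synthetic-cohort spec.
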