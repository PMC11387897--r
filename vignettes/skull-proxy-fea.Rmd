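---
title: "Comparative skull feeding biomechanics with linear tetrahedral finite elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative skull feeding biomechanics with linear tetrahedral finite elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skullfea)
```

## The question the package answers

Comparative feeding biomechanics asks how skull *shape*, as distinct from
skull *size*, governs the stresses a vertebrate skull experiences while
biting. The workflow implemented here is the one used throughout the
paleobiomechanics literature for crania and mandibles: mesh the skull with
four-node tetrahedra, anchor it at the jaw joints, load it with jaw-adductor
muscle tractions and bite-point forces, solve the linear elastostatic
problem, and compare models by a mesh-density-robust scalar summary — the
mesh-weighted arithmetic mean (MWAM) of element von Mises stress — under two
loading regimes: each model's own (actual-size) muscle forces, and forces
rescaled so that every model carries the same force per unit surface area as
a chosen reference (surface-area-equalized), which removes size and leaves
shape.

Because real specimen meshes are large, proprietary and heterogeneous, the
package ships a deterministic parametric generator of skull-*proxy* meshes
carrying exactly the loading topology used on real skulls. Every stage of
the pipeline is therefore testable offline against analytic oracles, and the
same code paths accept externally meshed models through a plain-text
tetrahedral format.

## Mechanical model and assumptions

The solver implements small-strain, linear elastostatics on four-node
(constant-strain) tetrahedra:

* **Element**: the CST tetrahedron. Strain is spatially constant per
  element, `e = B u_e`, with the 6 x 12 strain-displacement matrix built
  from the shape-function gradients; the element stiffness is
  `K_e = V_e * t(B) D B`.
* **Material**: homogeneous and isotropic per model. The default is
  cortical bone measured on sub-adult *Alligator mississippiensis* skulls —
  Young's modulus 15,000 MPa, Poisson's ratio 0.29 — the conventional
  stand-in for extinct archosaur bone. Teeth, sutures and trabecular
  heterogeneity are not separately modeled; this matches the standard
  comparative setup, where relative (not absolute) stress is the target.
* **Procedure**: static. Loads are applied gradually with no inertial
  effects, so one sparse symmetric positive-definite solve per load case.
* **Units**: a consistent N-mm-MPa system (lengths mm, forces N, moduli
  and stresses MPa). Adductor areas are quoted in cm^2, the unit in which
  adductor-chamber areas are reported, and converted only at the muscle-
  force boundary (1 cm^2 = 100 mm^2).

Constraints are applied by row/column elimination of the reduced system, so
constrained displacements are *exactly* zero, and reactions are recovered as
`K u - f` on the eliminated rows; the reaction sum balances the applied
loads to solver precision, which the test suite asserts. The default linear
solver is a sparse Cholesky factorization (`Matrix::Cholesky`); above a
configurable DOF threshold (200,000 by default) a Jacobi-preconditioned
conjugate-gradient fallback with relative-residual tolerance 1e-10 is used
instead, so externally supplied meshes far larger than the packaged proxies
remain solvable.

Stress is recovered per element as `s = D B u_e`; von Mises stress is the
rotation-invariant

```
vm = sqrt(0.5 * ((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2))
```

of the principal stresses, and the maximum principal strain is the largest
eigenvalue of the (tensor-shear) strain tensor, computed with a vectorized
trigonometric closed form that the tests cross-check against `eigen()`.

## Loading topology

The loading layout mirrors the one applied to real crania and mandibles:

* **Joints**: six fully fixed nodes — three per quadrate hinge (cranium) or
  articular hinge (mandible) — giving 18 constrained DOFs, enough to remove
  all six rigid-body modes with minimal over-constraint.
* **Bite points**: ten nodes, five per side, arranged in two anterior tooth
  rows (ventral on crania, dorsal on mandibles). Two treatments are
  available: `bite = "load"` applies an external point load split evenly
  over the ten nodes (the literal published procedure; the bite magnitude is
  not published, so it is a user input, defaulting to zero and direction
  (0, 0, -1)); `bite = "constrain"` instead fixes the bite nodes along the
  bite axis so the bite force emerges as a reaction — the common alternative
  formulation. The default is `load`.
* **Muscles**: total adductor force is estimated by the subtemporal-fenestra
  method — adductor chamber cross-sectional area times the isometric
  specific muscle tension of 31.5 N/cm^2 — optionally split across named
  groups by fixed fractions (default: one pooled adductor group, since the
  total is scaled from a single chamber area). Published analyses apply
  resolved X,Y,Z force components that are not printed; here directions are
  resolved geometrically as "toward-point" vectors: unit vectors from each
  insertion node toward an anatomical target (ventral to the proxy for
  crania, dorsal for mandibles — the direction of adductor pull), averaged
  per group and re-normalized. Each group's force is divided evenly over the
  nodes of its insertion patch, so per-node loads sum back to the group
  total exactly.

## Surface-area-equalized scaling

To compare shapes at equal size, muscle forces are rescaled so every model
carries the reference model's force-to-surface-area ratio:

```
F_model,g = F_ref,g * (SA_model / SA_ref)
```

The published wording ("muscle force component values were scaled to the
reference") admits two readings — applying the reference's absolute forces
to every model, or normalizing force per surface area. This package adopts
the force/SA normalization: it is the standard way to remove size in
comparative FEA (stress scales as force/length^2, and surface area scales
as length^2, so isometric copies of one shape then stress identically —
the operational meaning of "account for only shape", asserted to 1e-6
relative in the tests). The alternative reading is available by passing
explicit per-group forces to `build_load_case()`, since it amounts to a
different choice of `reference_forces`.

## The MWAM statistic

Models meshed from different sources (CT vs surface scans) have very
different element-size distributions, which biases a plain mean of
per-element stress. The mesh-weighted arithmetic mean

```
MWAM = sum(v_i * V_i) / sum(V_i)
```

weights each element's value by its volume and removes that bias. The
same weighting is applied by default to the mean maximum principal strain
(a plain mean is available via `strain_weighting = "plain"`; published
strain means do not state their weighting, and both are reported in the
CSV output) and to the stress quantiles, which use the volume-weighted
empirical distribution.

## Muscle-force sensitivity analysis

Muscle reconstructions of extinct taxa are uncertain, so each model is
re-solved with muscle forces 10% above and below baseline and compared by
the symmetric percent difference

```
pd(a, b) = |a - b| / ((a + b) / 2) * 100
```

which reproduces all twelve published percentage columns of the worked
cranial and mandibular sensitivity tables from their printed baseline and
perturbed means (asserted in the test suite to better than four significant
figures).

Two perturbation modes exist. In `global` mode all muscle loads scale
together; for a linear, purely muscle-loaded model the solution scales
exactly with the load, so the percent differences are the load-independent
constants `100*0.1/1.05 = 9.5238` (up) and `100*0.1/0.95 = 10.5263`
(down). This makes global mode a solver verification oracle rather than an
interesting measurement. The published per-taxon results deviate from those
constants (one cranial mean even *decreases* under +10% forces), which is
only possible if the perturbations were applied per muscle group with
re-resolved components. The default mode is therefore `per_muscle`: each
group is perturbed in turn while the others stay at baseline, and the
group-wise perturbed MWAMs are averaged per direction — one defensible
reading of an aggregation that is not spelled out in print; the per-group
detail table is always attached to the result so other aggregations can be
formed. With a single pooled group, `per_muscle` reduces to `global`
exactly. The cause of the published stress decrease under increased forces
cannot be reproduced from the printed information and is not a target of
this package.

## The synthetic proxy generator

`generate_proxy()` builds a tapered-wedge solid: rectangular cross-sections
lofted along the length axis, both dimensions shrinking linearly to
`anterior_taper` times their posterior values. A structured hexahedral grid
is split into six tetrahedra per cell (the Freudenthal decomposition —
conforming across cells and uniformly oriented, at the cost of a mild
directional bias that a 5-tet split would trade for face bookkeeping).
Node sets are selected purely geometrically as the nearest distinct nodes
to analytic anchor points, so labeling is stable under node reordering.
Presets:

| parameter | cranium | mandible | meaning |
|---|---|---|---|
| `length` | 300 mm | 300 mm | posterior-to-anterior extent |
| `posterior_width` | 140 mm | 110 mm | posterior section width |
| `posterior_depth` | 100 mm | 45 mm | posterior section depth |
| `anterior_taper` | 0.35 | 0.30 | anterior/posterior section ratio |
| `robusticity` | 1 | 1 | multiplier on posterior depth |
| `adductor_area` | 25 cm^2 | 25 cm^2 | muscle force = area x 31.5 N/cm^2 |
| `resolution` | 10 | 10 | element layers along the length |

The dimensions are sized like a small tyrannosauroid skull (~30 cm), and
25 cm^2 of adductor chamber gives a ~790 N pooled muscle force, in the
range estimated for small tyrannosauroids; the packaged `example_family()`
doubles it isometrically (3,150 N — near published estimates for
mid-sized tyrannosaurids) and adds a robust morph with 1.5x posterior
depth and a 120 cm^2 chamber. Proxies are solid (infilled), matching the
infilling that surface-scan-derived study models undergo; an optional
`fenestra` window cuts a through-hole to emulate cranial openings. The
`seed` parameter only feeds optional interior-node jitter (default 0), so
default geometry is purely analytic and byte-reproducible.

What the proxies deliberately do **not** emulate: real cranial anatomy
(individual bones, sutures, teeth as separate materials), curved tooth
rows, internal cavities, or scan/retrodeformation artifacts. Passing tests
on proxies therefore demonstrates the correctness of the solver, loading,
scaling and statistics machinery — not that any particular fossil's
absolute stress values are reproduced, which would require the original
specimen meshes and unpublished muscle vectors.

## Numerical choices

* Vertex merge tolerance for STL input: 1e-6 mm (STL stores vertices per
  facet); degenerate triangles are dropped after merging and contribute
  zero area.
* Negative-volume tetrahedra are repaired by swapping two node indices
  rather than rejected — external meshers emit mixed orientations; an
  exactly zero volume is an error naming the element.
* Element quality: the patch test (uniform uniaxial stress reproduced to
  ~1e-14) verifies consistency; bending convergence of CST elements is
  slow from below, so the cantilever verification uses a through-depth-
  refined mesh (100 x 4 x 20 element layers on a 40 x 4 x 4 mm beam,
  48,000 tets) where the tip deflection is within ~3% of the Timoshenko
  closed form `PL^3/3EI + PL/(kGA)`, with monotone error decrease over
  three refinement levels. Proxy comparisons use resolutions 6-10 (a few
  hundred to a few thousand elements), where solves take well under a
  second and the *comparative* statistics are stable.
* Weighted quantiles use the left-continuous inverse of the volume-weighted
  empirical CDF; ties in element values are resolved by the stable sort
  order, which is immaterial for volume-weighted summaries.
* Equality of `sum(reactions) + sum(loads)` is asserted at 1e-6 relative to
  the load magnitude; displacement-level oracles at 1e-8 to 1e-12 depending
  on the conditioning of the case.

## Known limitations

* Linear kinematics and material only: no contact, no geometric
  nonlinearity, no orthotropy or heterogeneity, no dynamics.
* Constant-strain tetrahedra are the deliberately chosen element (they are
  the de facto standard for fossil FEA), but they are stiff in bending;
  absolute deflections on coarse meshes underestimate, which is why
  comparisons rely on MWAM ratios between models meshed alike.
* The bite-force magnitude in `load` mode and the per-tooth spatial extent
  of bite node rows are free parameters; published sources do not state
  them.
* Crania and mandibles are always analyzed as separate models, never as an
  articulated pair.

## A minimal session

```{r example, eval = FALSE}
model <- generate_proxy(proxy_params("cranium", adductor_area = 25))
lc <- build_load_case(model, bite = bite_config("load", magnitude = 800))
field <- solve_fe(model$mesh, material_properties(), lc)
summarize_field(field)
run_sensitivity(model, material_properties(), lc, mode = "per_muscle")
```

The full comparative study — actual-size and surface-area-equalized runs,
sensitivity, CSV tables, VTK fields and a manifest — is driven by a YAML
configuration through `run_study()`, or from a shell via the thin wrapper
in `inst/scripts/skullfea.R`.
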