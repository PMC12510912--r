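---
title: "Methods: geometry reduced-order modeling of glymphatic function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry reduced-order modeling of glymphatic function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements: the
models and their assumptions, the parameters and where their values come
from, the numerical choices, and what the synthetic validation does and does
not establish.

## The problem

Finite-element models of brain solute transport and tissue fluid pressure
are defined on subject-specific meshes derived from MRI.  Each subject's
mesh has its own topology and degree-of-freedom count, so solutions on
different subjects cannot be combined directly, and every new subject
requires a full high-fidelity solve.  Geometry reduced-order modeling works
around this by noting that the *images* all live on a common grid: an
image-to-image deformable registration yields a map `φ_i` from subject `i`
to a target subject, and applying `φ_i` to the nodes of subject `i`'s mesh
transports its precomputed solution into the target anatomy.  A library of
transported solutions then spans a low-dimensional space in which the
target's problem can be solved at a small fraction of the full cost.

The offline cost (per-subject solves, registrations, the SVD) is paid once;
the online cost per new forward solve is a dense `d × d` system, with `d`
in the tens.  This is the regime in which parameter sweeps, sensitivity
analyses and estimation loops on patient-specific geometry become feasible.

## Pipeline

1. **Snapshots.** Solve the model full-order on each of `M` library
   subjects (`solve_model()`).
2. **Deformations.** Either the closed-form inter-subject maps of the
   synthetic cohort (`analytic_deformation()`, the ground truth) or the
   in-repo demons registration of the rasterized images (`register()`).
3. **Transport.** Deform subject meshes node-wise (`deform_mesh()`; nodal
   coefficient values ride along with the nodes) and evaluate at the target
   space's dof coordinates (`transfer_field()`): exact finite-element
   interpolation where the deformed mesh covers the target dof, and a
   normalized Gaussian-weighted average of the `k = 8` nearest source dof
   values (kernel width `σ = 1.0 ×` the local source mesh size) in the thin
   boundary band left uncovered by imperfect registration.  Both branches
   reproduce constants exactly and stay inside the convex hull of the
   source values.
4. **Reduction.** Stack the `M` transported snapshots column-wise
   (`build_snapshots()`), compute the SVD (`pod()`), project the target's
   assembled operators (`project_system()`: `A_rb = UᵀAU`, `F_rb = UᵀF`),
   solve the dense reduced system directly (`solve_reduced()`), and lift
   (`lift()`: `u = U u_rb`).

Transported snapshots do not satisfy the target's boundary conditions
exactly, and the span of the transported set is not a conforming subspace
of the target's function space; this is the structural reason reduced
errors plateau rather than vanish, and it is measured (boundary drift is a
reported diagnostic in the transfer tests).

The change-of-variables identity behind step 3 is verified directly: the
model forms can be assembled in pulled-back form (gradients composed with
the inverse-transpose deformation Jacobian, measures scaled by its
determinant, facet measures by the tangential stretch), and for affine maps
this agrees with direct assembly on the mapped mesh to rounding error.
Geometry-dependent data normalizations — the arterial influx
`Q_in = B_in / |∂Ω_pial|` — are evaluated in the *deformed* configuration,
which is what makes that identity exact.

## The two models

### Two-compartment tracer transport (model A, P2 elements)

Steady-state tracer concentrations in the extracellular space (ECS, `c_e`)
and perivascular spaces (PVS, `c_p`):

```
-∇·(n_e D_e ∇c_e) =  π_ep (c_p - c_e)
-∇·(n_p D_p ∇c_p) = -π_ep (c_p - c_e) - π_pb c_p
-n_e D_e ∇c_e · n = k_e (c_e - c_CSF^α)   on ∂Ω_α
-n_p D_p ∇c_p · n = k_p (c_p - c_CSF^α)   on ∂Ω_α
```

for `α ∈ {pial, ventricle}`.  Defaults (`model_a_params()`): volume
fractions `n_e = 0.2`, `n_p = 0.02`; diffusion `D_e = 1.3e-4`,
`D_p = 3.9e-4` mm²/s; exchange `π_ep = 2.9e-2` 1/s; clearance
`π_pb = 2.0e-8` 1/s (a low-clearance variant); surface conductivities
`k_e = 1.0e-5`, `k_p = 3.7e-4` mm/s.  The CSF boundary concentration is the
bi-exponential bolus `c_CSF^α(t) = (a_α/φ)(e^{-t/τ₂} - e^{-t/τ₁})` with
`a_pial = 0.52`, `a_ventricle = 0.2`, `φ = 0.2`, `τ₁ = 4.43e4` s,
`τ₂ = 8.5e4` s, evaluated at its peak.  The published formula for this
profile is typographically corrupted in print; the reconstruction implemented here
is the one whose closed-form stationary point,
`t* = ln(τ₂/τ₁)/(1/τ₁ − 1/τ₂) = 16.7 h` (3 s.f.), reproduces the stated
peak time, while alternative readings peak elsewhere or are monotone.  The
closed form is cross-checked against a numerical maximization in the tests.

With these constants the exchange term dominates diffusion
(`√(nD/π_ep) ≈ 0.03 mm`), so `c_e ≈ c_p` away from boundaries and the
combined field varies smoothly between the two boundary values — the
solutions are boundary-condition-driven, which is exactly what makes their
cross-geometry transport informative.

### Seven-network MPET (model B, P1 elements)

Steady Darcy pressures in seven overlapping networks — arterial `a`,
capillary `c`, venous `v`, their perivascular spaces `pa, pc, pv`, and the
extracellular space `e`:

```
-∇·(κ_i/μ_i ∇p_i) = Σ_{j≠i} ω_ij (p_j - p_i)
```

In its printed form the right-hand side of this model carries the opposite sign, which
is anti-dissipative (exchange would run *up* pressure gradients); the
standard MPET convention implemented here conserves mass pairwise (`ω`
symmetric, zero diagonal) and is dissipative.  Permeabilities `κ_i` (m²,
converted to mm² at load) and the eight nonzero `ω_ij` (1/(Pa·s)) follow
the base parameterization; elastic deformation terms are outside scope
(steady, rigid-matrix variant).

Pre-infusion boundary conditions: arterial Neumann influx
`κ_a∇p_a·n = Q_in = B_in/|∂Ω_pial|` on the pial surface; capillary Neumann
efflux `κ_c∇p_c·n = −Q_prod/|∂Ω_vent|` on the ventricle (choroid-plexus CSF
production, `Q_prod = 0.33 ml/min` as printed, implemented with the printed
sign); Robin anchors `β₁((p_DS+p_CSF)/2 − p_v)`, `β₂(p_CSF − p_pa)`,
`β₃((p_DS+p_CSF)/2 − p_pv)` on the pial surface with `p_DS = 8.4 mmHg`,
`β₁ = β₂ = 1e-3`, `β₃ = 1e-7`; homogeneous Neumann elsewhere.

**Values not fixed by the published parameter tables** (they defer to a
separate reference implementation): the viscosities (defaults `μ_blood = 2.67e-3` Pa·s for
`a, c, v`; `μ_CSF = 7.0e-4` Pa·s for the CSF-filled networks), the CSF
reference pressure (`p_CSF = 10 mmHg`) and the total arterial inflow
`B_in`.  `B_in = 2.0` mm³/s was chosen once so that the influx-attributable
arterial pressure drop on the reference synthetic geometry is of order
10 mmHg (measured: 10.2 mmHg), and was not revisited.  All three are
config-exposed and must be overridden for any quantitative claim about real
tissue.

A note on flow directions at desk scale: `Q_prod` is a physiological 3D
total applied to a small 2D analog domain, so the capillary sink dominates
the network balance and the *mean* arterial pressure can sit below the mean
venous pressure with defaults.  The influx-direction property (arterial
above venous) is therefore tested under influx-only conditions
(`Q_prod = 0`), where source placement forces it.

## The synthetic cohort

Each subject is an annulus: a star-shaped outer (pial) curve
`R(θ) = R₀(1 + Σ_{k=3..8} a_k cos(kθ + ψ_k))` about the origin and an
elliptic ventricle about a jittered centre.  Draws: `R₀ ~ U(55, 65)` mm,
`a_k ~ U(0, 0.04)` (so `Σ|a_k| < 0.3` always holds and the curve stays
star-shaped), phases `U(0, 2π)`, ventricle centre `U(−3, 3)²` mm, ventricle
semi-axes `U(6, 10)` mm (healthy-like) or `U(14, 22)` mm (iNPH-like) —
ventriculomegaly as the single systematic group difference.  The default
acceptance cohort is 28 healthy-like + 12 iNPH-like subjects, the same
≈70/30 composition as the clinical cohort the generator emulates, scaled to
desk size.  Cohort generation is bit-reproducible from the master seed, and
each subject records its own seed.

**Meshes** are structured annular triangulations in `(θ, ρ)` coordinates
(`ρ` the normalized annular coordinate, 0 at the ventricle and 1 at the
pial boundary), with boundary facets marked pial (1) and ventricle (2).  At
the default `h = 1.5` mm a subject has ≈5·10³ nodes, i.e. ≈4·10⁴ dofs for
the P2 two-compartment model and ≈3.5·10⁴ for the P1 MPET model — a
deliberate scale reduction from clinical meshes (~10⁵ nodes, ~10⁶ dofs)
chosen so the full pipeline (40 subjects × 2 models, two targets,
leave-one-out reduction) runs in minutes on one CPU.

**Images.** `rasterize()` produces a 160 × 160 single-slice image at 1 mm
(the field of view covers the largest admissible geometry with a ≥5 voxel
margin): zero outside the parenchyma, and inside the annulus a radial ramp
`0.4 + 0.6ρ` modulated by a weak multi-harmonic texture
`1 + (0.08 cos 7θ + 0.08 sin 4θ + 0.06 cos(11θ + 3πρ)) sin(πρ)`, with a
one-voxel anti-aliased boundary band.  The texture matters: a purely radial
profile is invariant under any sliding along its iso-intensity contours, so
no intensity-driven registration could recover the tangential part of the
true deformation — the problem would be ill-posed by construction.  Tying
the texture to the annular *material* coordinates emulates internal T1
contrast and makes the closed-form inter-subject map the global optimum of
intensity matching; the texture vanishes at both boundaries so edge
intensities are unaffected.

**Ground-truth maps.** The closed-form map preserves the angle about the
ventricle centre and the annular coordinate `ρ`, scales the ventricle
interior radially and shifts the exterior; it is smooth, orientation
preserving (`det J > 0` across the annulus, verified by scan), and exactly
transports both the geometry and the image texture.  Sampled on the image
grid it becomes an ordinary displacement field; forward and backward fields
compose to the identity within interpolation error.

## Registration

`register()` is a deterministic multi-resolution diffusion-regularized
demons scheme: three levels (4×, 2×, 1× downsampling), 100 iterations per
level, SSD metric, the classic demons force (whose normalization bounds
each step at half a voxel), per-iteration force smoothing `σ_update = 1`
voxel, accumulated-field smoothing `σ_total = 1.5` voxels, centre-of-mass
initialization.  On seeded synthetic pairs it recovers the closed-form
deformation to a mean of 0.4–0.8 voxels over the annulus interior, reduces
SSD by ≥ 10×, and produces strictly positive Jacobian determinants; these
gates are package-defined (the clinical reference pipeline reports no
registration accuracy to calibrate against).  Demons is not symmetric;
forward/backward inverse consistency is reported as a diagnostic, not
asserted.  Externally computed displacement fields in the documented NIfTI
convention (world-mm, identity-plus-displacement) can be substituted via
`load_external_field()` — with real data that is the intended route, with
the in-repo demons as the self-contained stand-in.

The experiment drivers take `backend = "analytic"` or `"demons"`; the
acceptance computations use the analytic backend to isolate
reduction-and-transport error from registration error, a separation the
synthetic setting exists to provide.

## Numerical choices

* **Elements and quadrature.** Lagrange P1/P2 on straight triangles;
  volume quadrature of degree `2·order` (3-point degree-2, 6-point
  degree-4 rules), 3-point Gauss on facets — exact for all bilinear forms
  used.  Dof ordering is deterministic: vertices in node order, then edge
  midpoints in lexicographic vertex-pair order; multi-field vectors are
  field-major (`ñ = n·D`), which makes snapshot stacking well defined.
* **Norms.** All reported errors are function-space L2 norms via the
  consistent mass matrix (`‖u‖² = uᵀMu`), not Euclidean coefficient norms;
  for P2 the two differ.  Multi-field norms are root-sum-square of
  per-field norms; per-field errors are also reported.
* **Solvers.** Sparse Cholesky (LU fallback) with a relative-residual check
  at `1e-10` for the full problem; dense direct solve with residual
  `< 1e-12` for the reduced system; a conjugate-gradient oracle
  cross-checks the direct solve in the tests.
* **Point location.** Uniform-grid spatial hashing with an all-cells
  brute-force oracle; the containment test is orientation-independent, so
  cells inverted by an imperfect registration are tolerated in transfer
  (and counted/warned about in `deform_mesh()`).
* **POD.** Euclidean inner product on coefficient vectors, matching the
  Frobenius-norm optimality statement; no per-field scaling by default
  (concentrations and pressures are stacked as-is).  Basis signs are fixed
  deterministically (largest-magnitude entry positive) for
  bit-reproducibility.  The squared-Frobenius Eckart–Young identity is
  asserted for every `d` in the tests.  The target's own solution is always
  excluded from its snapshot set (leave-one-out) except in the dedicated
  inclusion-exactness oracle, where `d = M` and the reduced solution must
  reproduce the full solution to `1e-8` (Galerkin exactness for symmetric
  coercive systems).
* **Convergence verification** uses a manufactured solution on a structured
  rectangle rather than a curved domain: with straight-edged cells a
  chorded curved boundary contributes an `O(h²)` geometric error that would
  mask the P2 `O(h³)` rate, while the polygonal rectangle isolates the
  element order (observed rates ≈2 and ≈3.5).
* **Degenerate inputs.** Geometry draws that violate the annular-topology
  invariant are redrawn with an incremented seed (at most 100 attempts);
  non-star-shaped folds are rejected at construction; non-positive
  pullback Jacobians abort assembly with the offending location;
  extrapolation fails loudly if no source dof lies within `10σ`.

## What the synthetic validation does and does not show

On the default seeded cohort the leave-one-out reduced solutions reproduce
the full-order solutions to well under the 10% headline level at `d = 30`,
and the largest-basis two-compartment error on a healthy-like target is a
fraction of a percent — comfortably inside the ~2% reported for the
clinical reference subject at full basis size.  These margins are expected
to be favorable: the 2D annular geometries are smooth, the analytic backend
removes registration error, and the solution manifolds are
boundary-driven and low-dimensional.  What the synthetic suite establishes
is the *correctness of the machinery* — exact change-of-variables pullback,
constant preservation and convex-hull bounds in transfer, Eckart–Young and
Galerkin identities, conservation and comparative statics of the models —
and the *qualitative phenomenology*: subgroup structure in mapping errors
(healthy-like targets are better approximated by healthy-like sources),
singular-value decay over a cohort of geometries, error plateaus with
basis size, and order-of-magnitude solve-time reductions.  It does not
establish clinical error levels, which depend on cortical-fold geometry,
registration quality on real T1 images and 3D meshing — all outside this
package's scope (as are FreeSurfer segmentation, SVMTK meshing and the SyN
registration algorithm itself).

Timings (full assembly, projection overhead, full solve, reduced solve, and
their ratios per basis size) are reported by `experiment_timing()` and the
`report` CLI stage but never asserted: they are hardware-dependent.
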