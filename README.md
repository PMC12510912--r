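# grom — geometry-based reduced order modeling for brain solute transport

Patient-specific finite-element simulation of brain clearance is expensive:
every subject has their own anatomy, mesh and degrees of freedom, so
cohort-scale studies of glymphatic function quickly become intractable.
`grom` implements a geometry reduced-order-modeling workflow that makes
solutions computed on *other* subjects' geometries reusable on a new target
geometry:

1. **Registration.** Deformable image registration between T1-like intensity
   images yields a displacement field `φ_i` from each subject `i` to the
   target; because images share a common grid, the mapping is independent of
   the meshes.
2. **Snapshot transport.** Each precomputed solution `u_i` rides along with
   its deformed mesh `φ_i(Ω_i)` and is read off at the target mesh's degrees
   of freedom (finite-element interpolation inside cells, normalized
   Gaussian-weighted extrapolation in the thin uncovered boundary band),
   giving snapshots `û_i` on the target geometry.
3. **POD / Galerkin.** The snapshots are stacked into `X ∈ R^{ñ×M}`
   (`ñ = n·D` for `n` fields with `D` dofs each); the SVD `X = UΣVᵀ` gives
   the optimal rank-`d` basis (Eckart–Young:
   `‖X − U_d U_dᵀ X‖_F² = Σ_{i>d} σ_i²`).  The full operators are projected,
   `A_rb = UᵀAU`, `F_rb = UᵀF`, and the reduced system is solved directly —
   orders of magnitude smaller than the full problem.

Two steady-state models of glymphatic function are built in:

* **Two-compartment tracer transport** (P2 elements): concentrations
  `(c_e, c_p)` in the extracellular and perivascular spaces with exchange
  `π_ep(c_p − c_e)`, perivascular clearance to blood `π_pb c_p`, and Robin
  membrane conditions `−nD∇c·n = k(c − c_CSF^α)` on the pial and ventricular
  surfaces, where `c_CSF^α(t) = (a_α/φ)(e^{−t/τ₂} − e^{−t/τ₁})` is an
  idealized CSF bolus evaluated at its peak (16.7 h).
* **Seven-network MPET** (P1 elements): Darcy-type pressures in arterial,
  capillary, venous, three perivascular and extracellular networks with
  symmetric pairwise exchange `ω_ij(p_j − p_i)`, arterial influx and
  capillary (choroid production) efflux as Neumann data, and Robin anchors
  on the venous and perivascular networks.

Because clinical MRI cannot ship with a package, `grom` includes a fully
synthetic 2D cohort generator: annular "brain-slice" geometries with a
star-shaped folded outer (pial) boundary and an elliptic inner (ventricle)
boundary, a healthy-like majority and an iNPH-like subgroup whose only
systematic difference is enlarged ventricles (the geometric hallmark of
idiopathic normal-pressure hydrocephalus).  The generator also provides the
*exact* inter-subject deformation in closed form, so registration and
reduction errors can be separated — something impossible with real data.

## Worked example

```r
library(grom)

# the CSF bolus profile peaks at 16.7 h; the tracer model is evaluated there
pa <- model_a_params()
peak_time(pa) / 3600
#> [1] 16.74755
csf_concentration(pa, pa$t_eval, "pial")      # boundary value, pial surface
#> [1] 0.6124895
csf_concentration(pa, pa$t_eval, "ventricle")
#> [1] 0.2355729

# a small seeded cohort: 5 healthy-like + 2 iNPH-like subjects
spec <- cohort_spec(n_healthy = 5, n_inph = 2, master_seed = 1, mesh_h = 3)
cohort <- sample_cohort(spec)
mesh <- build_mesh(cohort[[1]], 3)
mesh
#> <grom_mesh 1311 nodes, 2484 cells, 138 boundary facets (h=3 mm)>
field <- solve_model(mesh, pa, "A")
field
#> <grom_field [c_e, c_p] on P2 space, D=5106>
range(field$coeffs[1:field$space$D])   # c_e stays between the boundary values
#> [1] 0.2365674 0.6120074

# full pipeline: solve all subjects, map leave-one-out snapshots onto a
# healthy-like and an iNPH-like target, build POD bases, solve reduced
ex <- grom_experiment(spec, models = "A", d_values = c(2L, 6L),
                      subsets = "full", backend = "analytic")
subset(ex$reduced, field == "combined")
#>   target target_group model subset d    field      error
#>  sub-001      healthy     A   full 2 combined 0.01275020
#>  sub-001      healthy     A   full 6 combined 0.01172269
#>  sub-006         inph     A   full 2 combined 0.01598252
#>  sub-006         inph     A   full 6 combined 0.01813583
```

The `error` column is the relative L2 error (mass-matrix norm) of the
reduced solution against the stored full-order solution: with only six
snapshots a two-mode basis already reconstructs the tracer field on an
unseen geometry to ~1.3% on the healthy-like target.  Mapping-error
summaries by source subgroup (`experiment_mapping_error(ex)`), normalized
singular-value spectra (`ex$sigma`) and a timing table
(`experiment_timing(ex)`; projection overhead and full/reduced solve-time
ratio per basis size — reported, never asserted, since they are
hardware-dependent) complete the analysis.

## Command line

A staged, idempotent pipeline over an artifact directory:

```sh
Rscript scripts/grom.R synth    --config run.yaml --outdir out
Rscript scripts/grom.R solve    --config run.yaml --outdir out
Rscript scripts/grom.R register --config run.yaml --outdir out
Rscript scripts/grom.R map      --config run.yaml --outdir out
Rscript scripts/grom.R basis    --config run.yaml --outdir out
Rscript scripts/grom.R reduce   --config run.yaml --outdir out
Rscript scripts/grom.R eval     --config run.yaml --outdir out
Rscript scripts/grom.R report   --config run.yaml --outdir out
```

`run.yaml` overrides any subset of the defaults (`default_config()`):
cohort sizes and seeds, registration backend (`analytic` ground truth or
`demons`), model parameters, transfer and ROM options.  Meshes are written
as Gmsh MSH 4.1 and VTU, images and displacement fields as NIfTI
(single-slice volumes; displacements in world mm,
identity-plus-displacement convention).

## Limitations

The synthetic cohort is a desk-scale 2D analog (thousands, not millions, of
dofs; smooth fold patterns rather than cortical folds), so absolute error
levels are more favorable than on clinical meshes; the in-repo demons
registration is a pluggable stand-in validated against the closed-form
deformations, and externally computed displacement fields (e.g. ANTs warps)
can be loaded through `load_external_field()`.  See the methods vignette
(`vignettes/grom-methods.Rmd`) for the model assumptions, parameter
provenance and numerical choices.
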