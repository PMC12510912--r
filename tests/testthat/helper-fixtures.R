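# Shared fixtures, computed lazily and cached for the whole test run.
# Everything is generated in code from fixed seeds; no stored data.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# small desk-scale cohort (4 healthy-like + 2 iNPH-like, coarse meshes)
# with full-order solutions for both models
fix_cohort6 <- function() {
  cached("cohort6", {
    spec <- cohort_spec(n_healthy = 4, n_inph = 2, master_seed = 42,
                        mesh_h = 3)
    cohort <- sample_cohort(spec)
    meshes <- lapply(cohort, build_mesh, h = spec$mesh_h)
    pa <- model_a_params()
    pb <- model_b_params()
    list(spec = spec, cohort = cohort, meshes = meshes,
         params_a = pa, params_b = pb,
         sols_a = lapply(meshes, solve_model, params = pa, which = "A"),
         sols_b = lapply(meshes, solve_model, params = pb, which = "B"))
  })
}

# demons registration of a seeded healthy pair at the default study
# conditions, evaluated against the closed-form ground truth
fix_registration <- function() {
  cached("registration", {
    spec <- cohort_spec(n_healthy = 2, n_inph = 0, master_seed = 1)
    coh <- sample_cohort(spec)
    src <- coh[[1]]; dst <- coh[[2]]
    img_src <- rasterize(src, spec)
    img_dst <- rasterize(dst, spec)
    u <- register(moving = img_dst, fixed = img_src)
    nx <- spec$image_shape[1]
    xs <- -(nx - 1) / 2 + (seq_len(nx) - 1)
    pts <- cbind(rep(xs, times = nx), rep(xs, each = nx))
    ac <- annulus_coords(src, pts)
    interior <- ac$rho > 0.05 & ac$rho < 0.95
    truth <- analytic_map(src, dst, spec)
    ut <- cbind(as.vector(truth$ux), as.vector(truth$uy))[interior, ]
    ue <- apply_deformation(u, pts[interior, ]) - pts[interior, ]
    J <- deformation_jacobian(u, pts[interior, ])
    detJ <- J[, 1] * J[, 4] - J[, 2] * J[, 3]
    list(spec = spec, src = src, dst = dst, field = u,
         img_src = img_src, img_dst = img_dst,
         mean_err_vox = mean(sqrt(rowSums((ue - ut)^2))) / spec$voxel_size,
         ssd_ratio = attr(u, "ssd1") / attr(u, "ssd0"),
         frac_detJ_pos = mean(detJ > 0))
  })
}

# the full acceptance-scale experiment: 40 subjects, both models, both
# targets, analytic deformation backend, leave-one-out bases
fix_acceptance <- function() {
  cached("acceptance", {
    spec <- cohort_spec(n_healthy = 28, n_inph = 12, master_seed = 1,
                        mesh_h = 1.5)
    grom_experiment(spec, models = c("A", "B"), d_values = c(30L, 39L),
                    targets = "auto", subsets = "full", backend = "analytic")
  })
}

# transfer of one healthy-to-healthy pair from the small cohort
fix_transfer_pair <- function() {
  cached("transfer_pair", {
    cx <- fix_cohort6()
    def <- analytic_deformation(cx$cohort[[1]], cx$cohort[[2]])
    dm <- deform_mesh(cx$meshes[[1]], def)
    src <- cx$sols_a[[1]]
    sf <- fem_field(build_space(dm, 2, 2), dm, src$coeffs, src$field_names)
    tr <- transfer_field(sf, cx$meshes[[2]])
    list(deformed_mesh = dm, src_field = sf, transfer = tr,
         reference = cx$sols_a[[2]])
  })
}

# leave-one-out mapped tracer snapshots on the small cohort (target 2)
make_mapped_snapshots <- function() {
  cached("mapped_snaps6", {
    cx <- fix_cohort6()
    tgt <- 2L
    snaps <- list()
    for (i in setdiff(seq_along(cx$cohort), tgt)) {
      dm <- deform_mesh(cx$meshes[[i]],
                        analytic_deformation(cx$cohort[[i]], cx$cohort[[tgt]]))
      src <- cx$sols_a[[i]]
      sf <- fem_field(build_space(dm, 2, 2), dm, src$coeffs, src$field_names)
      snaps[[length(snaps) + 1L]] <- transfer_field(sf, cx$meshes[[tgt]])$field
    }
    list(target = tgt, snaps = snaps,
         system = assemble_model_a(cx$meshes[[tgt]], cx$params_a),
         reference = cx$sols_a[[tgt]])
  })
}
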