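# Snapshot transport: mesh deformation, field transfer with Gaussian
# boundary extrapolation, and the pulled-back variational identity.

test_that("mesh deformation preserves structure under trivial maps", {
  cx <- fix_cohort6()
  m <- cx$meshes[[1]]
  idd <- function_deformation(function(p) p,
                              function(p) cbind(1, 0, 0, 1)[rep(1, nrow(p)), ])
  dm <- deform_mesh(m, idd)
  expect_equal(dm$nodes, m$nodes)
  expect_identical(dm$cells, m$cells)
  expect_identical(dm$boundary_markers, m$boundary_markers)
  expect_equal(attr(dm, "n_inverted"), 0)
  # rigid translation preserves all cell areas exactly
  tr <- function_deformation(function(p) p + rep(c(5, -3), each = nrow(p)))
  dt <- deform_mesh(m, tr)
  a0 <- sort(abs(grom:::signed_areas(m$nodes, m$cells)))
  a1 <- sort(abs(grom:::signed_areas(dt$nodes, dt$cells)))
  expect_equal(a1, a0, tolerance = 1e-12)
})

test_that("deformed boundary nodes land on the target boundary curves", {
  fx <- fix_transfer_pair()
  cx <- fix_cohort6()
  dm <- fx$deformed_mesh
  dst <- cx$cohort[[2]]
  for (mk in c(1L, 2L)) {
    bn <- unique(as.vector(
      dm$boundary_edges[dm$boundary_markers == mk, , drop = FALSE]))
    ac <- annulus_coords(dst, dm$nodes[bn, , drop = FALSE])
    want <- if (mk == 1L) 1 else 0
    dev <- abs(ac$r - (ac$r_v + want * (ac$R - ac$r_v)))
    expect_lt(max(dev), 0.5 * cx$spec$voxel_size)
  }
})

test_that("transfer is exact on identical geometry and preserves constants", {
  cx <- fix_cohort6()
  m <- cx$meshes[[1]]
  sp <- build_space(m, 2, 2)
  # identity deformation, source mesh == target mesh: exact at dofs
  fld <- cx$sols_a[[1]]
  tr <- transfer_field(fld, m)
  expect_equal(tr$field$coeffs, fld$coeffs, tolerance = 1e-12)
  expect_equal(tr$report$n_extrapolated, 0)
  # idempotence at dofs on identical geometries
  tr2 <- transfer_field(tr$field, m)
  expect_equal(tr2$field$coeffs, tr$field$coeffs, tolerance = 1e-12)
  # constants survive across a real deformation (weights normalize)
  fx <- fix_transfer_pair()
  cfld <- fem_field(fx$src_field$space, fx$src_field$mesh,
                    rep(2.5, fx$src_field$space$n_dofs))
  trc <- transfer_field(cfld, cx$meshes[[2]])
  expect_equal(trc$field$coeffs, rep(2.5, trc$field$space$n_dofs),
               tolerance = 1e-12)
  expect_gt(trc$report$n_extrapolated, 0)  # the band exercises extrapolation
})

test_that("linear fields transfer exactly within covered cells", {
  cx <- fix_cohort6()
  src <- cx$cohort[[1]]
  m <- cx$meshes[[1]]
  # same geometry parameters: the closed-form deformation is the identity
  def <- analytic_deformation(src, src)
  dm <- deform_mesh(m, def)
  sp <- build_space(dm, 2, 1)
  lin <- fem_field(sp, dm, sp$dof_coords[, 1])
  tr <- transfer_field(lin, m)
  sp_t <- tr$field$space
  expect_lt(max(abs(tr$field$coeffs - sp_t$dof_coords[, 1])), 1e-9)
})

test_that("transferred values stay within the source value bounds", {
  fx <- fix_transfer_pair()
  lo <- min(fx$src_field$coeffs); hi <- max(fx$src_field$coeffs)
  tol <- 1e-10 * (hi - lo)
  expect_gt(min(fx$transfer$field$coeffs), lo - tol)
  expect_lt(max(fx$transfer$field$coeffs), hi + tol)
  # report is complete
  rep <- fx$transfer$report
  expect_equal(rep$n_interpolated + rep$n_extrapolated,
               fx$transfer$field$space$n_dofs / 2)
})

test_that("boundary-condition drift after transfer is measurable", {
  fx <- fix_transfer_pair()
  cx <- fix_cohort6()
  # diagnostic: sup over pial boundary dofs of |transferred - reference|
  m <- cx$meshes[[2]]
  sp <- fx$transfer$field$space
  bn <- unique(as.vector(sp$bedge_dofs[m$boundary_markers == 1L, ]))
  drift <- max(abs(fx$transfer$field$coeffs[bn] - fx$reference$coeffs[bn]))
  expect_true(is.finite(drift) && drift >= 0)
})

test_that("pulled-back assembly matches direct assembly for affine maps", {
  cx <- fix_cohort6()
  m <- cx$meshes[[1]]
  S <- matrix(c(1.1, 0.05, -0.03, 0.95), 2, 2)
  b <- c(2, -1)
  aff <- function_deformation(
    function(p) t(S %*% t(p)) + rep(b, each = nrow(p)),
    function(p) matrix(rep(c(S[1, 1], S[1, 2], S[2, 1], S[2, 2]), nrow(p)),
                       ncol = 4, byrow = TRUE))
  ma <- m
  ma$nodes <- t(S %*% t(m$nodes)) + rep(b, each = nrow(m$nodes))
  for (which in c("A", "B")) {
    sys_pb <- if (which == "A") assemble_model_a(m, cx$params_a, deformation = aff)
              else assemble_model_b(m, cx$params_b, deformation = aff)
    sys_dir <- if (which == "A") assemble_model_a(ma, cx$params_a)
               else assemble_model_b(ma, cx$params_b)
    expect_lt(max(abs(sys_pb$A - sys_dir$A)), 1e-10 * max(abs(sys_dir$A)))
    expect_lt(max(abs(sys_pb$F - sys_dir$F)), 1e-10 * max(abs(sys_dir$F)))
  }
})

test_that("modified-form residual vanishes for the identity deformation", {
  cx <- fix_cohort6()
  idd <- function_deformation(function(p) p,
                              function(p) cbind(1, 0, 0, 1)[rep(1, nrow(p)), ])
  expect_lt(modified_form_residual(cx$sols_a[[1]], idd, cx$params_a, "A"),
            1e-10)
  expect_lt(modified_form_residual(cx$sols_b[[1]], idd, cx$params_b, "B"),
            1e-10)
})

test_that("modified-form residual shrinks under mesh refinement", {
  cx <- fix_cohort6()
  src <- cx$cohort[[1]]; dst <- cx$cohort[[2]]
  def <- analytic_deformation(src, dst)
  res <- vapply(c(4, 2), function(h) {
    m <- build_mesh(src, h)
    fld <- solve_model(m, cx$params_a, "A")
    modified_form_residual(fld, def, cx$params_a, "A")
  }, numeric(1))
  expect_lt(res[2], res[1])
})

test_that("non-positive deformation Jacobians are rejected in pullback", {
  cx <- fix_cohort6()
  fold <- function_deformation(function(p) cbind(-p[, 1], p[, 2]),
                               function(p) cbind(-1, 0, 0, 1)[rep(1, nrow(p)), ])
  expect_error(assemble_model_a(cx$meshes[[1]], cx$params_a,
                                deformation = fold),
               "non-positive")
})

test_that("mapping error is zero for identical fields and scales linearly", {
  fx <- fix_transfer_pair()
  ref <- fx$reference
  expect_equal(unname(mapping_error(ref, ref)), c(0, 0))
  delta <- fem_field(ref$space, ref$mesh,
                     ref$coeffs * 0.01, ref$field_names)
  one <- fem_field(ref$space, ref$mesh, ref$coeffs + delta$coeffs,
                   ref$field_names)
  two <- fem_field(ref$space, ref$mesh, ref$coeffs + 2 * delta$coeffs,
                   ref$field_names)
  e1 <- mapping_error(one, ref); e2 <- mapping_error(two, ref)
  expect_equal(unname(e2), unname(2 * e1), tolerance = 1e-10)
})
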