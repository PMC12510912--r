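# Synthetic cohort: geometry parameterization, sampling, meshing,
# rasterization and the closed-form inter-subject maps.

test_that("cohort sampling is deterministic and respects group structure", {
  spec <- cohort_spec(n_healthy = 2, n_inph = 1, master_seed = 7)
  a <- sample_cohort(spec)
  b <- sample_cohort(spec)
  expect_identical(a, b)
  expect_equal(vapply(a, function(p) p$group, character(1)),
               c("healthy", "healthy", "inph"))

  big <- sample_cohort(cohort_spec(n_healthy = 70, n_inph = 31,
                                   master_seed = 3))
  expect_length(big, 101)
  expect_equal(sum(vapply(big, function(p) p$group, character(1)) == "inph"),
               31)
  # iNPH-like ventricles are drawn from the enlarged range
  vent <- t(vapply(big, function(p) p$vent_axes, numeric(2)))
  grp <- vapply(big, function(p) p$group, character(1))
  expect_true(all(vent[grp == "inph", ] >= 14 & vent[grp == "inph", ] <= 22))
  expect_true(all(vent[grp == "healthy", ] >= 6 & vent[grp == "healthy", ] <= 10))
})

test_that("sampled geometries keep annular topology (dense angular scan)", {
  coh <- sample_cohort(cohort_spec(n_healthy = 3, n_inph = 3, master_seed = 11))
  th <- seq(0, 2 * pi, length.out = 10001)[-10001]
  for (p in coh) {
    gap <- outer_radius_from(p, th) - boundary_radius(p, th, "ventricle")
    expect_gt(min(gap), 0)
  }
})

test_that("boundary radius evaluates folds and ellipses correctly", {
  p0 <- geometry_params("flat", "healthy", R0 = 60, fold_amps = rep(0, 6),
                        fold_phases = rep(0, 6), vent_axes = c(8, 8))
  th <- seq(0, 2 * pi, length.out = 17)
  expect_equal(boundary_radius(p0, th, "outer"), rep(60, 17))
  # single k=3 mode with zero phase: R(0) = 1.04 R0
  p3 <- geometry_params("k3", "healthy", R0 = 60,
                        fold_amps = c(0.04, 0, 0, 0, 0, 0),
                        fold_phases = rep(0, 6), vent_axes = c(8, 8))
  expect_equal(boundary_radius(p3, 0, "outer"), 60 * 1.04)
  # equal semi-axes: ventricle radius is constant
  expect_equal(boundary_radius(p0, th, "ventricle"), rep(8, 17))
  # invalid folds rejected
  expect_error(geometry_params("bad", "healthy", 60, rep(0.06, 6),
                               rep(0, 6), vent_axes = c(8, 8)),
               "star-shaped")
})

test_that("meshes carry complete boundary markers and match the exact area", {
  p <- sample_cohort(cohort_spec(2, 0, master_seed = 5))[[1]]
  m <- build_mesh(p, 2)
  expect_setequal(unique(m$boundary_markers), c(1L, 2L))
  # every boundary edge of the triangulation is marked exactly once:
  # edges appearing in exactly one cell must equal the marked set
  all_e <- rbind(m$cells[, 1:2], m$cells[, 2:3], m$cells[, c(3, 1)])
  key <- paste(pmin(all_e[, 1], all_e[, 2]), pmax(all_e[, 1], all_e[, 2]))
  tab <- table(key)
  bkey <- paste(pmin(m$boundary_edges[, 1], m$boundary_edges[, 2]),
                pmax(m$boundary_edges[, 1], m$boundary_edges[, 2]))
  expect_setequal(names(tab)[tab == 1], bkey)

  # area against numeric quadrature of the boundary curves
  th <- seq(0, 2 * pi, length.out = 40001)[-40001]
  area_exact <- mean(boundary_radius(p, th, "outer")^2) * pi -
    pi * prod(p$vent_axes)
  m15 <- build_mesh(p, 1.5)
  expect_lt(abs(mesh_area(m15) - area_exact) / area_exact, 0.01)
  # halving h reduces the boundary-approximation area error
  err_coarse <- abs(mesh_area(build_mesh(p, 3)) - area_exact)
  err_fine <- abs(mesh_area(m15) - area_exact)
  expect_lt(err_fine, err_coarse)
})

test_that("rasterized images match the geometry", {
  spec <- cohort_spec(2, 0, master_seed = 5)
  p <- sample_cohort(spec)[[1]]
  img <- rasterize(p, spec)
  # ventricle centre voxel is zero
  expect_equal(sample_image(img, matrix(p$vent_center, 1)), 0)
  # just inside the outer boundary the intensity approaches 1
  th <- pi / 3
  R <- outer_radius_from(p, th)
  pt <- p$vent_center + (R - 2) * c(cos(th), sin(th))
  expect_gt(sample_image(img, matrix(pt, 1)), 0.85)
  # support area vs mesh area within 2%
  area_img <- sum(img$data > 0) * prod(img$spacing)
  expect_lt(abs(area_img - mesh_area(build_mesh(p, 1.5))) / area_img, 0.02)
  # mesh nodes lie in positive-intensity voxels (1-voxel boundary tolerance)
  m <- build_mesh(p, 2)
  vals <- sample_image(img, m$nodes)
  rho <- annulus_coords(p, m$nodes)$rho
  interior <- rho > 0.05 & rho < 0.95
  expect_true(all(vals[interior] > 0))
})

test_that("image field of view is enforced", {
  p <- sample_cohort(cohort_spec(2, 0, master_seed = 5))[[1]]
  small <- cohort_spec(2, 0, master_seed = 5, image_shape = c(64L, 64L))
  expect_error(rasterize(p, small), "field of view")
})

test_that("closed-form maps are exact on boundaries and invertible", {
  spec <- cohort_spec(2, 1, master_seed = 9)
  coh <- sample_cohort(spec)
  src <- coh[[1]]; dst <- coh[[3]]  # healthy -> iNPH-like
  # identity map: zero displacement
  self <- analytic_map(src, src, spec)
  expect_lt(max(abs(self$ux)), 1e-9)
  expect_lt(max(abs(self$uy)), 1e-9)
  # ventricle boundary maps onto ventricle boundary at matched angle
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  rv <- boundary_radius(src, th, "ventricle")
  pts <- cbind(src$vent_center[1] + rv * cos(th),
               src$vent_center[2] + rv * sin(th))
  mapped <- apply_deformation(analytic_deformation(src, dst), pts)
  rv_d <- boundary_radius(dst, th, "ventricle")
  want <- cbind(dst$vent_center[1] + rv_d * cos(th),
                dst$vent_center[2] + rv_d * sin(th))
  expect_lt(max(sqrt(rowSums((mapped - want)^2))), 0.1)
  # positive Jacobian determinant across the annulus
  set.seed(1)
  thr <- runif(500, 0, 2 * pi); rhor <- runif(500, 0.02, 0.98)
  rvr <- boundary_radius(src, thr, "ventricle")
  Rr <- outer_radius_from(src, thr)
  qp <- cbind(src$vent_center[1] + (rvr + rhor * (Rr - rvr)) * cos(thr),
              src$vent_center[2] + (rvr + rhor * (Rr - rvr)) * sin(thr))
  J <- deformation_jacobian(analytic_deformation(src, dst), qp)
  expect_true(all(J[, 1] * J[, 4] - J[, 2] * J[, 3] > 0))
  # grid-sampled forward and backward compose to the identity
  f_ab <- analytic_map(src, dst, spec)
  f_ba <- analytic_map(dst, src, spec)
  mid <- apply_deformation(f_ab, qp)
  back <- apply_deformation(f_ba, mid)
  expect_lt(max(sqrt(rowSums((back - qp)^2))), 0.2)
})

test_that("cohort manifests round-trip through JSON", {
  coh <- sample_cohort(cohort_spec(2, 1, master_seed = 13))
  path <- tempfile(fileext = ".json")
  write_manifest(coh, path)
  back <- read_manifest(path)
  for (i in seq_along(coh)) {
    expect_equal(back[[i]]$R0, coh[[i]]$R0)
    expect_equal(back[[i]]$vent_axes, coh[[i]]$vent_axes)
    expect_equal(back[[i]]$group, coh[[i]]$group)
  }
})
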