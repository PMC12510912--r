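# Finite-element core: spaces, assembly, solves, point location and norms.

test_that("space enumeration gives the expected dof counts", {
  m1 <- grom_mesh(nodes = rbind(c(0, 0), c(1, 0), c(0, 1)),
                  cells = rbind(c(1, 2, 3)),
                  boundary_edges = rbind(c(1, 2), c(2, 3), c(3, 1)),
                  boundary_markers = c(1L, 1L, 2L))
  expect_equal(build_space(m1, 1)$D, 3)
  expect_equal(build_space(m1, 2)$D, 6)
  expect_error(build_space(m1, 3), "unsupported order")
  # on a generated mesh: D_2 = D_1 + number of unique edges
  p <- sample_cohort(cohort_spec(2, 0, master_seed = 5))[[1]]
  m <- build_mesh(p, 4)
  e <- rbind(m$cells[, 1:2], m$cells[, 2:3], m$cells[, c(3, 1)])
  n_edges <- length(unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  expect_equal(build_space(m, 2)$D, build_space(m, 1)$D + n_edges)
})

test_that("pure-Neumann operators annihilate constants", {
  p <- sample_cohort(cohort_spec(2, 0, master_seed = 5))[[1]]
  m <- build_mesh(p, 3)
  for (ord in 1:2) {
    sp <- build_space(m, ord)
    sys <- assemble_operator(m, sp, diffusion = 1)
    expect_lt(max(abs(sys$A %*% rep(1, sp$D))), 1e-12 * max(abs(sys$A)))
  }
})

test_that("large Robin conductivity enforces the boundary value", {
  p <- sample_cohort(cohort_spec(2, 0, master_seed = 5))[[1]]
  m <- build_mesh(p, 3)
  sp <- build_space(m, 2)
  sys <- assemble_operator(m, sp, diffusion = 1, robin = list(
    list(field = 1L, marker = 1L, k = 1e6, g = 2.75),
    list(field = 1L, marker = 2L, k = 1e6, g = 2.75)))
  sol <- solve_full(sys)
  expect_lt(max(abs(sol$coeffs - 2.75)), 1e-6)
})

test_that("exchange coupling conserves mass across field blocks", {
  p <- sample_cohort(cohort_spec(2, 0, master_seed = 5))[[1]]
  m <- build_mesh(p, 3)
  sp <- build_space(m, 1, n_fields = 2L)
  W <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  sys <- assemble_operator(m, sp, diffusion = c(1, 1), exchange = W)
  set.seed(4)
  x <- rnorm(sp$n_dofs)
  # diffusion blocks annihilate constants; exchange cancels pairwise, so
  # summing A x over all dofs of both blocks must give zero
  expect_lt(abs(sum(sys$A %*% x)), 1e-9 * sqrt(sum(x^2)))
})

test_that("assembled systems are symmetric", {
  cx <- fix_cohort6()
  sysA <- assemble_model_a(cx$meshes[[1]], cx$params_a)
  sysB <- assemble_model_b(cx$meshes[[1]], cx$params_b)
  for (sys in list(sysA, sysB)) {
    asym <- max(abs(sys$A - Matrix::t(sys$A)))
    expect_lt(asym, 1e-10 * max(abs(sys$A)))
  }
})

test_that("direct solve matches a conjugate-gradient oracle", {
  cx <- fix_cohort6()
  sys <- assemble_model_a(cx$meshes[[1]], cx$params_a, order = 1L)
  direct <- solve_full(sys)$coeffs
  # plain CG, written here as the independent oracle
  A <- sys$A; b <- sys$F
  x <- numeric(length(b)); r <- b; pdir <- r
  rs <- sum(r^2)
  for (it in 1:20000) {
    Ap <- as.numeric(A %*% pdir)
    alpha <- rs / sum(pdir * Ap)
    x <- x + alpha * pdir
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    if (sqrt(rs_new) < 1e-14 * sqrt(sum(b^2))) break
    pdir <- r + (rs_new / rs) * pdir
    rs <- rs_new
  }
  expect_lt(max(abs(x - direct)) / max(abs(direct)), 1e-8)
})

test_that("manufactured solutions converge at the expected order", {
  D <- 2
  uex <- function(p) sin(pi * p[, 1]) * cos(pi * p[, 2] / 2)
  f <- function(p) D * (pi^2 + pi^2 / 4) * uex(p)
  gfun <- function(p) {
    gx <- pi * cos(pi * p[, 1]) * cos(pi * p[, 2] / 2)
    gy <- -pi / 2 * sin(pi * p[, 1]) * sin(pi * p[, 2] / 2)
    nx <- ifelse(abs(p[, 1] - 1) < 1e-9, 1, ifelse(abs(p[, 1]) < 1e-9, -1, 0))
    ny <- ifelse(abs(p[, 2] - 1) < 1e-9, 1, ifelse(abs(p[, 2]) < 1e-9, -1, 0))
    uex(p) + D * (gx * nx + gy * ny)
  }
  for (ord in 1:2) {
    errs <- vapply(c(8, 16, 32), function(n) {
      m <- mesh_rectangle(n, n)
      sp <- build_space(m, ord)
      sys <- assemble_operator(m, sp, diffusion = D,
                               robin = list(list(field = 1L, marker = 1L,
                                                 k = 1, g = gfun)),
                               sources = list(list(field = 1L, f = f)))
      sol <- solve_full(sys)
      l2_norm(fem_field(sp, m, sol$coeffs - uex(sp$dof_coords)))
    }, numeric(1))
    rate <- mean(log2(errs[-3] / errs[-1]))
    expect_gt(rate, ord + 0.7)
  }
})

test_that("interpolation is exact at dofs and matches the brute-force scan", {
  cx <- fix_cohort6()
  m <- cx$meshes[[1]]
  sp <- build_space(m, 2)
  fld <- fem_field(sp, m, sin(sp$dof_coords[, 1] / 10) +
                     cos(sp$dof_coords[, 2] / 10))
  # Lagrange property: values at dof coordinates equal the coefficients
  at_dofs <- locate_and_interpolate(fld, sp$dof_coords[1:50, ])
  expect_true(all(at_dofs$found))
  expect_equal(at_dofs$values[, 1], fld$coeffs[1:50], tolerance = 1e-12)
  # far outside the domain: not found
  out <- locate_and_interpolate(fld, rbind(c(500, 500)))
  expect_false(out$found[1])
  # spatial hash equals the all-cells scan on random interior points
  p <- cx$cohort[[1]]
  set.seed(5)
  th <- runif(100, 0, 2 * pi); rho <- runif(100, 0.05, 0.95)
  rv <- boundary_radius(p, th, "ventricle"); R <- outer_radius_from(p, th)
  pts <- cbind(p$vent_center[1] + (rv + rho * (R - rv)) * cos(th),
               p$vent_center[2] + (rv + rho * (R - rv)) * sin(th))
  hash <- locate_and_interpolate(fld, pts, method = "hash")
  brute <- locate_and_interpolate(fld, pts, method = "brute")
  expect_equal(hash$found, brute$found)
  expect_equal(hash$values, brute$values)
})

test_that("L2 norms use the mass matrix and closed forms", {
  cx <- fix_cohort6()
  m <- cx$meshes[[1]]
  sp <- build_space(m, 2)
  cfld <- fem_field(sp, m, rep(3, sp$D))
  expect_equal(l2_norm(cfld), 3 * sqrt(mesh_area(m)), tolerance = 1e-10)
  # relative error of a field against itself is zero
  expect_equal(relative_l2(cfld, cfld), 0)
  # P1 interpolant of sin(pi x / 60) converges to the quadrature value
  quad_ref <- function(mm) {
    # independent high-order quadrature of sin^2 over the mesh (7-pt rule
    # per triangle via simple subdivision sampling)
    tot <- 0
    for (cell in seq_len(nrow(mm$cells))) {
      v <- mm$nodes[mm$cells[cell, ], ]
      bary <- rbind(c(1, 1, 1) / 3, c(.6, .2, .2), c(.2, .6, .2), c(.2, .2, .6))
      w <- c(-27, 25, 25, 25) / 48
      a2 <- abs((v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
                  (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])) / 2
      pts <- bary %*% v
      tot <- tot + a2 * sum(w * sin(pi * pts[, 1] / 60)^2)
    }
    sqrt(tot)
  }
  errs <- vapply(c(4, 2), function(h) {
    mm <- build_mesh(cx$cohort[[1]], h)
    s1 <- build_space(mm, 1)
    ff <- fem_field(s1, mm, sin(pi * s1$dof_coords[, 1] / 60))
    abs(l2_norm(ff) - quad_ref(mm))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  # zero reference is rejected
  zf <- fem_field(sp, m, rep(0, sp$D))
  expect_error(relative_l2(cfld, zf), "zero")
})
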