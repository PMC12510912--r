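## Finite-element core: Lagrange P1/P2 spaces on triangles, assembly of
## diffusion + exchange + Robin forms, sparse solves, point location and
## interpolation, and mass-matrix L2 norms.  All coordinates in mm.

# --- reference element --------------------------------------------------

# volume quadrature on the reference triangle (0,0)-(1,0)-(0,1);
# weights sum to the reference area 1/2
tri_quadrature <- function(degree) {
  if (degree <= 2) {
    pts <- rbind(c(0.5, 0), c(0.5, 0.5), c(0, 0.5))
    w <- rep(1 / 6, 3)
  } else {
    a1 <- 0.445948490915965; w1 <- 0.223381589678011
    a2 <- 0.091576213509771; w2 <- 0.109951743655322
    b1 <- 1 - 2 * a1; b2 <- 1 - 2 * a2
    # barycentric (l1,l2,l3); xi = l2, eta = l3
    bar <- rbind(c(a1, a1, b1), c(a1, b1, a1), c(b1, a1, a1),
                 c(a2, a2, b2), c(a2, b2, a2), c(b2, a2, a2))
    pts <- bar[, 2:3]
    w <- c(w1, w1, w1, w2, w2, w2) / 2
  }
  list(pts = pts, w = w)
}

# 3-point Gauss on [0,1] (exact to degree 5) for facet integrals
edge_quadrature <- function() {
  s <- sqrt(3 / 5) / 2
  list(t = c(0.5 - s, 0.5, 0.5 + s), w = c(5, 8, 5) / 18)
}

# basis values at reference points (rows) for P1/P2; pts = (xi, eta)
basis_values <- function(order, pts) {
  l1 <- 1 - pts[, 1] - pts[, 2]; l2 <- pts[, 1]; l3 <- pts[, 2]
  if (order == 1) {
    cbind(l1, l2, l3)
  } else {
    cbind(l1 * (2 * l1 - 1), l2 * (2 * l2 - 1), l3 * (2 * l3 - 1),
          4 * l1 * l2, 4 * l2 * l3, 4 * l3 * l1)
  }
}

# reference gradients: array [n_basis, 2, n_pts]
basis_grads <- function(order, pts) {
  nq <- nrow(pts)
  if (order == 1) {
    g <- array(0, c(3, 2, nq))
    for (q in seq_len(nq)) {
      g[, , q] <- rbind(c(-1, -1), c(1, 0), c(0, 1))
    }
    return(g)
  }
  g <- array(0, c(6, 2, nq))
  for (q in seq_len(nq)) {
    xi <- pts[q, 1]; eta <- pts[q, 2]
    l1 <- 1 - xi - eta; l2 <- xi; l3 <- eta
    # d(l1)/d(xi,eta) = (-1,-1); l2: (1,0); l3: (0,1)
    g[1, , q] <- (4 * l1 - 1) * c(-1, -1)
    g[2, , q] <- (4 * l2 - 1) * c(1, 0)
    g[3, , q] <- (4 * l3 - 1) * c(0, 1)
    g[4, , q] <- 4 * (l2 * c(-1, -1) + l1 * c(1, 0))
    g[5, , q] <- 4 * (l3 * c(1, 0) + l2 * c(0, 1))
    g[6, , q] <- 4 * (l1 * c(0, 1) + l3 * c(-1, -1))
  }
  g
}

# edge trace basis at parameter t in [0,1]
edge_basis_values <- function(order, t) {
  if (order == 1) cbind(1 - t, t)
  else cbind((1 - t) * (1 - 2 * t), t * (2 * t - 1), 4 * t * (1 - t))
}

# --- function spaces ----------------------------------------------------

#' Build a Lagrange finite-element space
#'
#' Enumerates degrees of freedom deterministically: vertex dofs in node
#' order, then (for order 2) edge-midpoint dofs in lexicographic order of
#' the sorted vertex pair.  With `n_fields > 1` the global coefficient
#' vector is field-major: all `D` dofs of field 1, then field 2, etc., so a
#' multi-field solution has `n_fields * D` degrees of freedom.
#'
#' @param mesh a [grom_mesh()].
#' @param order polynomial order, 1 or 2.
#' @param n_fields number of scalar fields sharing the space.
#' @return An object of class `grom_space` with components `D` (dofs per
#'   field), `dof_coords`, `cell_dofs`, `bedge_dofs`.
#' @export
build_space <- function(mesh, order, n_fields = 1L) {
  if (!order %in% c(1L, 2L)) stop("unsupported order: ", order, " (use 1 or 2)")
  N <- nrow(mesh$nodes)
  if (order == 1) {
    sp <- list(order = 1L, n_fields = as.integer(n_fields), D = N,
               dof_coords = mesh$nodes, cell_dofs = mesh$cells,
               bedge_dofs = mesh$boundary_edges)
  } else {
    cells <- mesh$cells
    e_all <- rbind(cells[, c(1, 2)], cells[, c(2, 3)], cells[, c(3, 1)])
    lo <- pmin(e_all[, 1], e_all[, 2]); hi <- pmax(e_all[, 1], e_all[, 2])
    key <- (lo - 1) * as.double(N) + hi
    ukey <- sort(unique(key))
    eidx <- match(key, ukey)
    m <- nrow(cells)
    cell_dofs <- cbind(cells,
                       N + eidx[seq_len(m)],
                       N + eidx[m + seq_len(m)],
                       N + eidx[2 * m + seq_len(m)])
    ulo <- floor((ukey - 1) / N) + 1; uhi <- ukey - (ulo - 1) * N
    mid <- (mesh$nodes[ulo, , drop = FALSE] + mesh$nodes[uhi, , drop = FALSE]) / 2
    be <- mesh$boundary_edges
    bkey <- (pmin(be[, 1], be[, 2]) - 1) * as.double(N) + pmax(be[, 1], be[, 2])
    bidx <- match(bkey, ukey)
    sp <- list(order = 2L, n_fields = as.integer(n_fields),
               D = N + length(ukey),
               dof_coords = rbind(mesh$nodes, mid),
               cell_dofs = cell_dofs,
               bedge_dofs = cbind(be, N + bidx))
  }
  sp$n_dofs <- sp$n_fields * sp$D
  sp$mesh_hash <- mesh_hash(mesh)
  class(sp) <- "grom_space"
  sp
}

#' @export
print.grom_space <- function(x, ...) {
  cat(sprintf("<grom_space P%d, %d field(s), D=%d per field (%d total)>\n",
              x$order, x$n_fields, x$D, x$n_dofs))
  invisible(x)
}

#' Finite-element field
#'
#' A coefficient vector on a mesh/space pair, field-major layout.
#'
#' @param space a [build_space()] object.
#' @param mesh the mesh the space was built on.
#' @param coeffs numeric vector of length `space$n_dofs`.
#' @param field_names character vector naming the fields.
#' @return An object of class `grom_field`.
#' @export
fem_field <- function(space, mesh, coeffs, field_names = NULL) {
  stopifnot(length(coeffs) == space$n_dofs, all(is.finite(coeffs)))
  if (is.null(field_names)) field_names <- paste0("f", seq_len(space$n_fields))
  stopifnot(length(field_names) == space$n_fields)
  structure(list(space = space, mesh = mesh, coeffs = as.numeric(coeffs),
                 field_names = field_names), class = "grom_field")
}

#' @export
print.grom_field <- function(x, ...) {
  cat(sprintf("<grom_field [%s] on P%d space, D=%d>\n",
              paste(x$field_names, collapse = ", "), x$space$order, x$space$D))
  invisible(x)
}

field_matrix <- function(field) {
  matrix(field$coeffs, nrow = field$space$D, ncol = field$space$n_fields)
}

# --- geometry factors ---------------------------------------------------

cell_geometry <- function(mesh) {
  p1 <- mesh$nodes[mesh$cells[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$cells[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$cells[, 3], , drop = FALSE]
  e1x <- p2[, 1] - p1[, 1]; e1y <- p2[, 2] - p1[, 2]
  e2x <- p3[, 1] - p1[, 1]; e2y <- p3[, 2] - p1[, 2]
  det <- e1x * e2y - e2x * e1y
  list(p1 = p1, e1x = e1x, e1y = e1y, e2x = e2x, e2y = e2y, det = det)
}

# physical gradients of all basis functions at one quadrature point:
# returns list(gx, gy) each [n_cells x n_basis]
phys_grads <- function(geo, refg_q) {
  nb <- nrow(refg_q)
  gx <- matrix(0, length(geo$det), nb)
  gy <- matrix(0, length(geo$det), nb)
  for (i in seq_len(nb)) {
    gxi <- refg_q[i, 1]; gei <- refg_q[i, 2]
    gx[, i] <- (geo$e2y * gxi - geo$e1y * gei) / geo$det
    gy[, i] <- (-geo$e2x * gxi + geo$e1x * gei) / geo$det
  }
  list(gx = gx, gy = gy)
}

# metric factors of a deformation at physical points: components of
# |det J| * J^{-1} J^{-T} (c11, c12, c22) and |det J|
metric_factors <- function(deformation, points) {
  J <- deformation_jacobian(deformation, points)
  det <- J[, 1] * J[, 4] - J[, 2] * J[, 3]
  if (any(det <= 0)) {
    bad <- which(det <= 0)[1]
    stop(sprintf("non-positive deformation Jacobian (det=%.3g) at point (%.2f, %.2f)",
                 det[bad], points[bad, 1], points[bad, 2]))
  }
  # J = [j11 j12; j21 j22] stored as columns (j11, j12, j21, j22)
  j11 <- J[, 1]; j12 <- J[, 2]; j21 <- J[, 3]; j22 <- J[, 4]
  # J^{-1} = [j22 -j12; -j21 j11] / det
  c11 <- (j22^2 + j12^2) / det
  c12 <- -(j21 * j22 + j11 * j12) / det
  c22 <- (j21^2 + j11^2) / det
  list(c11 = c11, c12 = c12, c22 = c22, det = det)
}

# --- scalar building blocks --------------------------------------------

# stiffness matrix for unit diffusion on one scalar field; with a
# deformation the integrand becomes (|detJ| J^{-1}J^{-T} grad u) . grad v
scalar_stiffness <- function(mesh, space, deformation = NULL) {
  geo <- cell_geometry(mesh)
  quad <- tri_quadrature(2 * space$order)
  refg <- basis_grads(space$order, quad$pts)
  nb <- ncol(space$cell_dofs)
  m <- nrow(mesh$cells)
  vals <- matrix(0, m, nb * nb)
  phiq <- basis_values(space$order, quad$pts)
  for (q in seq_along(quad$w)) {
    pg <- phys_grads(geo, refg[, , q])
    wdet <- quad$w[q] * geo$det
    if (is.null(deformation)) {
      c11 <- 1; c12 <- 0; c22 <- 1
    } else {
      # physical quadrature point coordinates
      xq <- geo$p1[, 1] + quad$pts[q, 1] * geo$e1x + quad$pts[q, 2] * geo$e2x
      yq <- geo$p1[, 2] + quad$pts[q, 1] * geo$e1y + quad$pts[q, 2] * geo$e2y
      mf <- metric_factors(deformation, cbind(xq, yq))
      c11 <- mf$c11; c12 <- mf$c12; c22 <- mf$c22
    }
    k <- 0L
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      k <- k + 1L
      vals[, k] <- vals[, k] + wdet *
        (c11 * pg$gx[, i] * pg$gx[, j] +
         c12 * (pg$gx[, i] * pg$gy[, j] + pg$gy[, i] * pg$gx[, j]) +
         c22 * pg$gy[, i] * pg$gy[, j])
    }
  }
  ii <- jj <- matrix(0L, m, nb * nb)
  k <- 0L
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    k <- k + 1L
    ii[, k] <- space$cell_dofs[, i]
    jj[, k] <- space$cell_dofs[, j]
  }
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = as.vector(vals),
                       dims = c(space$D, space$D))
}

# consistent mass matrix on one scalar field (weight |detJ| under deformation)
scalar_mass <- function(mesh, space, deformation = NULL) {
  geo <- cell_geometry(mesh)
  quad <- tri_quadrature(2 * space$order)
  phi <- basis_values(space$order, quad$pts)
  nb <- ncol(space$cell_dofs)
  m <- nrow(mesh$cells)
  vals <- matrix(0, m, nb * nb)
  for (q in seq_along(quad$w)) {
    wdet <- quad$w[q] * geo$det
    if (!is.null(deformation)) {
      xq <- geo$p1[, 1] + quad$pts[q, 1] * geo$e1x + quad$pts[q, 2] * geo$e2x
      yq <- geo$p1[, 2] + quad$pts[q, 1] * geo$e1y + quad$pts[q, 2] * geo$e2y
      mf <- metric_factors(deformation, cbind(xq, yq))
      wdet <- wdet * mf$det
    }
    k <- 0L
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      k <- k + 1L
      vals[, k] <- vals[, k] + wdet * phi[q, i] * phi[q, j]
    }
  }
  ii <- jj <- matrix(0L, m, nb * nb)
  k <- 0L
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    k <- k + 1L
    ii[, k] <- space$cell_dofs[, i]
    jj[, k] <- space$cell_dofs[, j]
  }
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = as.vector(vals),
                       dims = c(space$D, space$D))
}

#' Mass matrix of a scalar field
#' @param mesh a [grom_mesh()].
#' @param space a [build_space()] object (one field is enough; the mass
#'   matrix is shared across fields).
#' @return Sparse `D x D` consistent mass matrix.
#' @export
mass_matrix <- function(mesh, space) scalar_mass(mesh, space)

# volume load vector int f v dx; f constant or function(points)->values
volume_load <- function(mesh, space, f, deformation = NULL, point_map = NULL) {
  geo <- cell_geometry(mesh)
  quad <- tri_quadrature(2 * space$order)
  phi <- basis_values(space$order, quad$pts)
  nb <- ncol(space$cell_dofs)
  F <- numeric(space$D)
  for (q in seq_along(quad$w)) {
    xq <- geo$p1[, 1] + quad$pts[q, 1] * geo$e1x + quad$pts[q, 2] * geo$e2x
    yq <- geo$p1[, 2] + quad$pts[q, 1] * geo$e1y + quad$pts[q, 2] * geo$e2y
    wdet <- quad$w[q] * geo$det
    if (!is.null(deformation)) {
      mf <- metric_factors(deformation, cbind(xq, yq))
      wdet <- wdet * mf$det
    }
    pts <- cbind(xq, yq)
    if (!is.null(point_map)) pts <- point_map(pts)
    fv <- if (is.function(f)) f(pts) else rep(f, nrow(pts))
    for (i in seq_len(nb)) {
      contrib <- wdet * fv * phi[q, i]
      F <- F + as.vector(tapply_sum(contrib, space$cell_dofs[, i], space$D))
    }
  }
  F
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# boundary mass matrix and load for a marker; scale under deformation is the
# tangential stretch |J tau|
boundary_terms <- function(mesh, space, marker, g = NULL,
                           deformation = NULL, point_map = NULL) {
  sel <- mesh$boundary_markers == marker
  if (!any(sel)) stop("mesh has no facets with marker ", marker)
  bd <- space$bedge_dofs[sel, , drop = FALSE]
  a <- mesh$nodes[mesh$boundary_edges[sel, 1], , drop = FALSE]
  b <- mesh$nodes[mesh$boundary_edges[sel, 2], , drop = FALSE]
  L <- sqrt(rowSums((b - a)^2))
  tau <- (b - a) / L
  eq <- edge_quadrature()
  phi <- edge_basis_values(space$order, eq$t)
  nb <- ncol(phi)
  ne <- nrow(bd)
  Mvals <- matrix(0, ne, nb * nb)
  Fvals <- matrix(0, ne, nb)
  for (q in seq_along(eq$w)) {
    px <- a[, 1] + eq$t[q] * (b[, 1] - a[, 1])
    py <- a[, 2] + eq$t[q] * (b[, 2] - a[, 2])
    scale <- rep(1, ne)
    if (!is.null(deformation)) {
      J <- deformation_jacobian(deformation, cbind(px, py))
      jx <- J[, 1] * tau[, 1] + J[, 2] * tau[, 2]
      jy <- J[, 3] * tau[, 1] + J[, 4] * tau[, 2]
      scale <- sqrt(jx^2 + jy^2)
    }
    wL <- eq$w[q] * L * scale
    k <- 0L
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      k <- k + 1L
      Mvals[, k] <- Mvals[, k] + wL * phi[q, i] * phi[q, j]
    }
    if (!is.null(g)) {
      pts <- cbind(px, py)
      if (!is.null(point_map)) pts <- point_map(pts)
      gv <- if (is.function(g)) g(pts) else rep(g, ne)
      for (i in seq_len(nb)) {
        Fvals[, i] <- Fvals[, i] + wL * gv * phi[q, i]
      }
    }
  }
  ii <- jj <- matrix(0L, ne, nb * nb)
  k <- 0L
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    k <- k + 1L
    ii[, k] <- bd[, i]; jj[, k] <- bd[, j]
  }
  M <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(Mvals), dims = c(space$D, space$D))
  F <- numeric(space$D)
  if (!is.null(g)) {
    for (i in seq_len(nb)) F <- F + tapply_sum(Fvals[, i], bd[, i], space$D)
  }
  list(M = M, F = F)
}

# --- assembled system ---------------------------------------------------

#' Assemble a multi-field diffusion/exchange/Robin system
#'
#' Builds the symmetric system for `n` coupled scalar fields
#' \deqn{-\nabla\cdot(D_f \nabla u_f) + \sum_g W_{fg}(u_f - u_g) + \delta_f u_f = s_f}
#' with Robin conditions \eqn{-D_f \nabla u_f \cdot n = k (u_f - g)} and
#' Neumann data \eqn{D_f \nabla u_f \cdot n = q} on marked boundary parts.
#' The exchange matrix `W` must be symmetric with zero diagonal, so the
#' exchange terms conserve mass pairwise (block row sums cancel).
#'
#' When a `deformation` is supplied, the forms are pulled back through it:
#' gradients are composed with the inverse transpose Jacobian and measures
#' scaled by its determinant, so assembling on the undeformed mesh
#' reproduces the system of the deformed geometry (change of variables).
#'
#' @param mesh a [grom_mesh()].
#' @param space a [build_space()] with `n_fields` fields.
#' @param diffusion numeric vector of per-field diffusion coefficients (> 0).
#' @param exchange optional `n x n` symmetric exchange-rate matrix (zero
#'   diagonal).
#' @param decay optional per-field linear decay rates (adds `decay_f * u_f`).
#' @param robin list of Robin terms, each `list(field=, marker=, k=, g=)`;
#'   `g` may be a constant or a `function(points)`.
#' @param neumann list of Neumann terms `list(field=, marker=, flux=)`,
#'   where `flux` is the value of \eqn{D \nabla u \cdot n}.
#' @param sources list of volume sources `list(field=, f=)`.
#' @param deformation optional deformation for pulled-back assembly.
#' @param point_map optional function mapping assembly points before
#'   coefficient evaluation (used with `deformation` when data live on the
#'   deformed geometry).
#' @return An object of class `grom_system` with sparse `A` and vector `F`.
#' @export
assemble_operator <- function(mesh, space, diffusion, exchange = NULL,
                              decay = NULL, robin = list(), neumann = list(),
                              sources = list(), deformation = NULL,
                              point_map = NULL) {
  n <- space$n_fields
  stopifnot(length(diffusion) == n, all(diffusion > 0))
  if (!is.null(exchange)) {
    stopifnot(nrow(exchange) == n, ncol(exchange) == n,
              max(abs(exchange - t(exchange))) < 1e-12 * (max(abs(exchange)) + 1),
              all(diag(exchange) == 0), all(exchange >= 0))
  }
  D <- space$D
  K1 <- scalar_stiffness(mesh, space, deformation)
  needs_mass <- !is.null(exchange) || !is.null(decay)
  M1 <- if (needs_mass) scalar_mass(mesh, space, deformation) else NULL

  off <- function(f) (f - 1L) * D
  blocks_i <- list(); blocks_j <- list(); blocks_x <- list()
  add_block <- function(fi, fj, S, coef = 1) {
    S <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
    blocks_i[[length(blocks_i) + 1L]] <<- S@i + 1L + off(fi)
    blocks_j[[length(blocks_j) + 1L]] <<- S@j + 1L + off(fj)
    blocks_x[[length(blocks_x) + 1L]] <<- S@x * coef
  }
  F <- numeric(n * D)

  for (f in seq_len(n)) add_block(f, f, K1, diffusion[f])
  if (needs_mass) {
    W <- if (is.null(exchange)) matrix(0, n, n) else exchange
    dec <- if (is.null(decay)) numeric(n) else decay
    cpl <- diag(rowSums(W) + dec, n) - W
    for (fi in seq_len(n)) for (fj in seq_len(n)) {
      if (cpl[fi, fj] != 0) add_block(fi, fj, M1, cpl[fi, fj])
    }
  }
  for (rb in robin) {
    bt <- boundary_terms(mesh, space, rb$marker, g = rb$g,
                         deformation = deformation, point_map = point_map)
    add_block(rb$field, rb$field, bt$M, rb$k)
    idx <- off(rb$field) + seq_len(D)
    F[idx] <- F[idx] + rb$k * bt$F
  }
  for (nm in neumann) {
    bt <- boundary_terms(mesh, space, nm$marker, g = nm$flux,
                         deformation = deformation, point_map = point_map)
    idx <- off(nm$field) + seq_len(D)
    F[idx] <- F[idx] + bt$F
  }
  for (sc in sources) {
    idx <- off(sc$field) + seq_len(D)
    F[idx] <- F[idx] + volume_load(mesh, space, sc$f, deformation, point_map)
  }
  A <- Matrix::sparseMatrix(i = unlist(blocks_i), j = unlist(blocks_j),
                            x = unlist(blocks_x), dims = c(n * D, n * D))
  structure(list(A = A, F = F, space = space, mesh = mesh,
                 symmetric = TRUE), class = "grom_system")
}

#' @export
print.grom_system <- function(x, ...) {
  cat(sprintf("<grom_system %d x %d, %d nonzeros>\n",
              nrow(x$A), ncol(x$A), Matrix::nnzero(x$A)))
  invisible(x)
}

#' Solve an assembled sparse system
#'
#' Uses a sparse Cholesky factorization for the symmetric positive definite
#' systems assembled here (LU fallback) and checks the relative residual.
#'
#' @param system a [assemble_operator()] result.
#' @param rtol residual tolerance for the post-solve check.
#' @return A list with `coeffs`, `residual`, `method` and `time` (seconds).
#' @export
solve_full <- function(system, rtol = 1e-10) {
  t0 <- proc.time()[["elapsed"]]
  A <- system$A
  x <- NULL; method <- "cholesky"
  if (isTRUE(system$symmetric)) {
    As <- Matrix::forceSymmetric(A)
    ch <- try(Matrix::Cholesky(As, LDL = FALSE), silent = TRUE)
    if (!inherits(ch, "try-error")) {
      x <- as.numeric(Matrix::solve(ch, system$F))
    }
  }
  if (is.null(x)) {
    method <- "lu"
    x <- try(as.numeric(Matrix::solve(A, system$F)), silent = TRUE)
    if (inherits(x, "try-error")) {
      stop("linear solve failed; system may be singular (no Robin/exchange ",
           "anchor for the constant kernel?)")
    }
  }
  res <- sqrt(sum((as.numeric(A %*% x) - system$F)^2)) /
    max(sqrt(sum(system$F^2)), .Machine$double.eps)
  if (is.finite(res) && res > rtol && sqrt(sum(system$F^2)) > 0) {
    warning(sprintf("solver residual %.2e exceeds tolerance %.1e", res, rtol))
  }
  list(coeffs = x, residual = res, method = method,
       time = proc.time()[["elapsed"]] - t0)
}

# --- point location and interpolation ----------------------------------

build_locator <- function(mesh) {
  m <- nrow(mesh$cells)
  xs <- matrix(mesh$nodes[mesh$cells, 1], m, 3)
  ys <- matrix(mesh$nodes[mesh$cells, 2], m, 3)
  xmin <- min(xs); xmax <- max(xs); ymin <- min(ys); ymax <- max(ys)
  nb <- max(8L, as.integer(ceiling(sqrt(m / 2))))
  dx <- (xmax - xmin) / nb; dy <- (ymax - ymin) / nb
  dx <- max(dx, 1e-12); dy <- max(dy, 1e-12)
  bx0 <- pmax(pmin(floor((apply(xs, 1, min) - xmin) / dx), nb - 1), 0)
  bx1 <- pmax(pmin(floor((apply(xs, 1, max) - xmin) / dx), nb - 1), 0)
  by0 <- pmax(pmin(floor((apply(ys, 1, min) - ymin) / dy), nb - 1), 0)
  by1 <- pmax(pmin(floor((apply(ys, 1, max) - ymin) / dy), nb - 1), 0)
  nrep <- (bx1 - bx0 + 1) * (by1 - by0 + 1)
  cell_id <- rep(seq_len(m), nrep)
  bins <- integer(sum(nrep))
  pos <- 1L
  for (c in seq_len(m)) {
    gx <- bx0[c]:bx1[c]; gy <- by0[c]:by1[c]
    nn <- length(gx) * length(gy)
    bins[pos:(pos + nn - 1L)] <- rep(gx, times = length(gy)) +
      rep(gy, each = length(gx)) * nb + 1L
    pos <- pos + nn
  }
  ord <- order(bins, cell_id)
  bins <- bins[ord]; cell_id <- cell_id[ord]
  starts <- c(1L, which(diff(bins) > 0) + 1L)
  bin_of <- bins[starts]
  lens <- diff(c(starts, length(bins) + 1L))
  start_lookup <- integer(nb * nb); len_lookup <- integer(nb * nb)
  start_lookup[bin_of] <- starts
  len_lookup[bin_of] <- lens
  list(nb = nb, xmin = xmin, ymin = ymin, dx = dx, dy = dy,
       cell_id = cell_id, start = start_lookup, len = len_lookup)
}

barycentric_pairs <- function(mesh, points, cells) {
  p1 <- mesh$nodes[mesh$cells[cells, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$cells[cells, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$cells[cells, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  l2 <- ((points[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (points[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])) / det
  l3 <- ((p2[, 1] - p1[, 1]) * (points[, 2] - p1[, 2]) -
           (p2[, 2] - p1[, 2]) * (points[, 1] - p1[, 1])) / det
  cbind(1 - l2 - l3, l2, l3)
}

#' Locate points in a mesh
#'
#' Finds, for each query point, a containing cell and its barycentric
#' coordinates.  `method = "hash"` uses a uniform-grid spatial hash;
#' `method = "brute"` scans all cells (the independent oracle).  Points in
#' inverted (negatively oriented) cells are still located: the barycentric
#' containment test is orientation-independent.
#'
#' @param mesh a [grom_mesh()].
#' @param points n x 2 matrix of query points.
#' @param method `"hash"` or `"brute"`.
#' @param tol barycentric tolerance for containment.
#' @return A list with integer `cell` (NA when not found) and `bary`
#'   (n x 3).
#' @export
locate_points <- function(mesh, points, method = c("hash", "brute"), tol = 1e-9) {
  method <- match.arg(method)
  points <- as_points(points)
  np <- nrow(points)
  cell <- rep(NA_integer_, np)
  bary <- matrix(NA_real_, np, 3)
  if (method == "brute") {
    for (p in seq_len(np)) {
      lam <- barycentric_pairs(mesh, points[rep(p, nrow(mesh$cells)), , drop = FALSE],
                               seq_len(nrow(mesh$cells)))
      ok <- which(rowSums(lam >= -tol) == 3)
      if (length(ok)) { cell[p] <- ok[1]; bary[p, ] <- lam[ok[1], ] }
    }
    return(list(cell = cell, bary = bary))
  }
  loc <- build_locator(mesh)
  bx <- pmax(pmin(floor((points[, 1] - loc$xmin) / loc$dx), loc$nb - 1), 0)
  by <- pmax(pmin(floor((points[, 2] - loc$ymin) / loc$dy), loc$nb - 1), 0)
  bin <- as.integer(bx + by * loc$nb + 1L)
  len <- loc$len[bin]
  has <- which(len > 0L)
  if (length(has)) {
    pt_idx <- rep(has, len[has])
    cand_pos <- sequence(len[has]) + rep(loc$start[bin[has]], len[has]) - 1L
    cand <- loc$cell_id[cand_pos]
    lam <- barycentric_pairs(mesh, points[pt_idx, , drop = FALSE], cand)
    ok <- rowSums(lam >= -tol) == 3
    if (any(ok)) {
      pi_ok <- pt_idx[ok]; cell_ok <- cand[ok]; lam_ok <- lam[ok, , drop = FALSE]
      ord <- order(pi_ok, cell_ok)
      pi_ok <- pi_ok[ord]; cell_ok <- cell_ok[ord]
      lam_ok <- lam_ok[ord, , drop = FALSE]
      keep <- !duplicated(pi_ok)
      cell[pi_ok[keep]] <- cell_ok[keep]
      bary[pi_ok[keep], ] <- lam_ok[keep, , drop = FALSE]
    }
  }
  list(cell = cell, bary = bary)
}

#' Interpolate a field at points
#'
#' Exact finite-element interpolation for points inside a cell; points not
#' contained in any cell are flagged not-found and their values set `NA`
#' (callers decide how to extrapolate).
#'
#' @param field a [fem_field()].
#' @param points n x 2 matrix of world coordinates.
#' @param method point-location method passed to [locate_points()].
#' @return A list with `values` (n x n_fields matrix) and logical `found`.
#' @export
locate_and_interpolate <- function(field, points, method = "hash") {
  points <- as_points(points)
  loc <- locate_points(field$mesh, points, method = method)
  found <- !is.na(loc$cell)
  U <- field_matrix(field)
  vals <- matrix(NA_real_, nrow(points), field$space$n_fields)
  if (any(found)) {
    idx <- which(found)
    lam <- loc$bary[idx, , drop = FALSE]
    phi <- if (field$space$order == 1) lam else
      cbind(lam[, 1] * (2 * lam[, 1] - 1), lam[, 2] * (2 * lam[, 2] - 1),
            lam[, 3] * (2 * lam[, 3] - 1),
            4 * lam[, 1] * lam[, 2], 4 * lam[, 2] * lam[, 3],
            4 * lam[, 3] * lam[, 1])
    dofs <- field$space$cell_dofs[loc$cell[idx], , drop = FALSE]
    for (f in seq_len(field$space$n_fields)) {
      acc <- numeric(length(idx))
      for (i in seq_len(ncol(phi))) acc <- acc + phi[, i] * U[dofs[, i], f]
      vals[idx, f] <- acc
    }
  }
  colnames(vals) <- field$field_names
  list(values = vals, found = found)
}

# --- norms --------------------------------------------------------------

#' L2 norm of a field
#'
#' Function-space norm computed with the consistent mass matrix,
#' \eqn{\|u\|_{L^2} = \sqrt{u^\top M u}} per field; the multi-field norm is
#' the square root of the sum of squared per-field norms.
#'
#' @param field a [fem_field()].
#' @param fields optional character or integer subset of fields.
#' @param per_field return one norm per field instead of the combined norm.
#' @return Numeric norm(s).
#' @export
l2_norm <- function(field, fields = NULL, per_field = FALSE) {
  M <- mass_matrix(field$mesh, field$space)
  U <- field_matrix(field)
  sel <- resolve_fields(field, fields)
  norms <- vapply(sel, function(f) {
    u <- U[, f]
    sqrt(max(0, sum(u * as.numeric(M %*% u))))
  }, numeric(1))
  names(norms) <- field$field_names[sel]
  if (per_field) norms else sqrt(sum(norms^2))
}

resolve_fields <- function(field, fields) {
  if (is.null(fields)) return(seq_len(field$space$n_fields))
  if (is.character(fields)) {
    sel <- match(fields, field$field_names)
    if (anyNA(sel)) stop("unknown field name(s): ",
                         paste(fields[is.na(sel)], collapse = ", "))
    sel
  } else as.integer(fields)
}

#' Relative L2 error between two fields on the same space
#'
#' @param field,reference [fem_field()] objects sharing mesh and space.
#' @param fields optional subset of fields.
#' @param per_field return per-field relative errors.
#' @return `||field - reference|| / ||reference||` in the mass-matrix norm.
#' @export
relative_l2 <- function(field, reference, fields = NULL, per_field = FALSE) {
  stopifnot(field$space$D == reference$space$D,
            field$space$n_fields == reference$space$n_fields,
            field$space$mesh_hash == reference$space$mesh_hash)
  diff <- fem_field(field$space, field$mesh, field$coeffs - reference$coeffs,
                    field$field_names)
  num <- l2_norm(diff, fields, per_field)
  den <- l2_norm(reference, fields, per_field)
  if (any(den == 0)) stop("reference field has zero L2 norm")
  num / den
}
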