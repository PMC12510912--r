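## Transport of snapshot solutions between geometries: mesh deformation,
## field transfer by interpolation with Gaussian-weighted boundary
## extrapolation, and verification of the pulled-back (modified-operator)
## variational identity.

#' General deformation from user functions
#'
#' Wraps a point map and (optionally) its Jacobian as a deformation object;
#' used for affine and other closed-form maps in verification studies.
#' When `jacobian` is `NULL` a central finite difference on `map` is used.
#'
#' @param map `function(points)` returning mapped n x 2 coordinates.
#' @param jacobian optional `function(points)` returning n x 4 Jacobian
#'   rows `(j11, j12, j21, j22)`.
#' @return An object of class `grom_function_deformation`.
#' @export
function_deformation <- function(map, jacobian = NULL) {
  structure(list(map = map, jac = jacobian), class = "grom_function_deformation")
}

#' @export
apply_deformation.grom_function_deformation <- function(deformation, points) {
  deformation$map(as_points(points))
}

#' @export
deformation_jacobian.grom_function_deformation <- function(deformation, points) {
  points <- as_points(points)
  if (!is.null(deformation$jac)) return(deformation$jac(points))
  d <- 1e-4
  px1 <- deformation$map(points + cbind(rep(d, nrow(points)), 0))
  px0 <- deformation$map(points - cbind(rep(d, nrow(points)), 0))
  py1 <- deformation$map(points + cbind(0, rep(d, nrow(points))))
  py0 <- deformation$map(points - cbind(0, rep(d, nrow(points))))
  cbind((px1[, 1] - px0[, 1]) / (2 * d), (py1[, 1] - py0[, 1]) / (2 * d),
        (px1[, 2] - px0[, 2]) / (2 * d), (py1[, 2] - py0[, 2]) / (2 * d))
}

#' Deform a mesh with a deformation field
#'
#' Moves the mesh nodes through the deformation; connectivity and boundary
#' markers are preserved.  Cells inverted by an imperfect deformation are
#' reported (attribute `n_inverted`, with a warning) but not repaired,
#' mirroring how imperfect registrations are handled in practice.
#'
#' @param mesh a [grom_mesh()].
#' @param deformation a deformation object.
#' @return The deformed mesh; attribute `n_inverted` counts cells with
#'   non-positive area after deformation.
#' @export
deform_mesh <- function(mesh, deformation) {
  new_nodes <- apply_deformation(deformation, mesh$nodes)
  ar <- signed_areas(new_nodes, mesh$cells)
  n_inv <- sum(ar <= 0)
  if (n_inv > 0) {
    warning(n_inv, " cell(s) inverted by the deformation; transfer will use ",
            "orientation-independent containment tests")
  }
  out <- mesh
  out$nodes <- new_nodes
  attr(out, "n_inverted") <- n_inv
  # bypass the constructor's orientation check: inverted cells are tolerated
  class(out) <- "grom_mesh"
  out
}

# mean edge length per cell, averaged onto dofs (local mesh size)
local_dof_h <- function(mesh, space) {
  p1 <- mesh$nodes[mesh$cells[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$cells[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$cells[, 3], , drop = FALSE]
  el <- (sqrt(rowSums((p2 - p1)^2)) + sqrt(rowSums((p3 - p2)^2)) +
           sqrt(rowSums((p1 - p3)^2))) / 3
  nb <- ncol(space$cell_dofs)
  acc <- numeric(space$D); cnt <- numeric(space$D)
  for (i in seq_len(nb)) {
    acc <- acc + tapply_sum(el, space$cell_dofs[, i], space$D)
    cnt <- cnt + tapply_sum(rep(1, length(el)), space$cell_dofs[, i], space$D)
  }
  acc / pmax(cnt, 1)
}

#' Transfer a field to a target mesh
#'
#' For every target degree of freedom: if its coordinate lies inside a cell
#' of the source mesh, the value is obtained by exact finite-element
#' interpolation; otherwise (typically a thin band at the boundary where
#' the deformed source mesh does not cover the target) the value is a
#' normalized Gaussian-weighted average of the `k_neighbors` nearest source
#' dof values, with kernel width `sigma = sigma_factor` times the local
#' source mesh size.  Both branches reproduce constants exactly and keep
#' transferred values inside the convex hull of the source values used.
#'
#' @param src_field a [fem_field()] on the (deformed) source mesh.
#' @param target_mesh the target [grom_mesh()].
#' @param k_neighbors number of source dofs used for extrapolation.
#' @param sigma_factor kernel width in units of the local source mesh size.
#' @return A list with `field` (a [fem_field()] on the target mesh) and
#'   `report` (class `grom_transfer_report`: `n_interpolated`,
#'   `n_extrapolated`, `max_extrapolation_distance`).
#' @export
transfer_field <- function(src_field, target_mesh, k_neighbors = 8L,
                           sigma_factor = 1.0) {
  sp_t <- build_space(target_mesh, src_field$space$order,
                      src_field$space$n_fields)
  res <- locate_and_interpolate(src_field, sp_t$dof_coords, method = "hash")
  vals <- res$values
  n_out <- sum(!res$found)
  max_dist <- 0
  if (n_out > 0) {
    src_coords <- src_field$space$dof_coords
    h_loc <- local_dof_h(src_field$mesh, src_field$space)
    U <- field_matrix(src_field)
    out_idx <- which(!res$found)
    k <- min(k_neighbors, nrow(src_coords))
    for (p in out_idx) {
      d2 <- (src_coords[, 1] - sp_t$dof_coords[p, 1])^2 +
        (src_coords[, 2] - sp_t$dof_coords[p, 2])^2
      nn <- order(d2)[seq_len(k)]
      sigma <- sigma_factor * h_loc[nn[1]]
      dmin <- sqrt(d2[nn[1]])
      if (dmin > 10 * sigma) {
        stop(sprintf(paste0("no source dofs within 10 sigma (%.2f mm) of target ",
                            "dof at (%.1f, %.1f); geometries grossly mismatched"),
                     10 * sigma, sp_t$dof_coords[p, 1], sp_t$dof_coords[p, 2]))
      }
      max_dist <- max(max_dist, dmin)
      w <- exp(-d2[nn] / (2 * sigma^2))
      w <- w / sum(w)
      vals[p, ] <- as.numeric(w %*% U[nn, , drop = FALSE])
    }
  }
  coeffs <- as.vector(vals)
  report <- structure(list(
    n_interpolated = sum(res$found), n_extrapolated = n_out,
    max_extrapolation_distance = max_dist,
    det_J_range = attr(src_field, "det_J_range") %||% c(NA_real_, NA_real_)),
    class = "grom_transfer_report")
  list(field = fem_field(sp_t, target_mesh, coeffs, src_field$field_names),
       report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.grom_transfer_report <- function(x, ...) {
  cat(sprintf("<transfer: %d interpolated, %d extrapolated (max dist %.3f mm)>\n",
              x$n_interpolated, x$n_extrapolated, x$max_extrapolation_distance))
  invisible(x)
}

#' Residual of a snapshot in the pulled-back (modified) variational form
#'
#' Assembles the model operators on the source mesh with the differential
#' operators modified to be consistent with the deformation (gradients
#' composed with the inverse-transpose Jacobian, measures scaled by its
#' determinant -- the change-of-variables pullback), applies them to the
#' snapshot coefficients, and returns the relative algebraic residual
#' `||A_hat u - F_hat|| / ||F_hat||`.  For the identity deformation this
#' equals the ordinary full-order residual.
#'
#' @param src_field the snapshot [fem_field()] on the original source mesh.
#' @param deformation the deformation to the target geometry.
#' @param params model parameters ([model_a_params()] or
#'   [model_b_params()]).
#' @param which `"A"` or `"B"`.
#' @return Relative residual (scalar).
#' @export
modified_form_residual <- function(src_field, deformation, params,
                                   which = c("A", "B")) {
  which <- match.arg(which)
  sys <- if (which == "A") {
    assemble_model_a(src_field$mesh, params, order = src_field$space$order,
                     deformation = deformation)
  } else {
    assemble_model_b(src_field$mesh, params, order = src_field$space$order,
                     deformation = deformation)
  }
  r <- as.numeric(sys$A %*% src_field$coeffs) - sys$F
  sqrt(sum(r^2)) / max(sqrt(sum(sys$F^2)), .Machine$double.eps)
}

#' Per-field mapping error of a transferred snapshot
#'
#' @param mapped,reference [fem_field()] objects on the same target
#'   mesh/space.
#' @return Named vector of per-field relative L2 errors.
#' @export
mapping_error <- function(mapped, reference) {
  relative_l2(mapped, reference, per_field = TRUE)
}
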