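## Proper orthogonal decomposition: snapshot matrices, SVD-based reduced
## bases, Galerkin projection of assembled operators, reduced solves and
## lifting back to the full space.

#' Stack snapshot fields into a snapshot matrix
#'
#' Each multi-field snapshot contributes one column of length
#' `n_fields * D` (field-major layout); the fields are treated as
#' independent components of one long state vector.
#'
#' @param fields list of [fem_field()] objects on the same mesh and space.
#' @param source_ids optional character provenance ids (one per snapshot).
#' @return An object of class `grom_snapshots` with dense matrix `X`.
#' @export
build_snapshots <- function(fields, source_ids = NULL) {
  stopifnot(length(fields) >= 1)
  sp <- fields[[1]]$space
  for (f in fields) {
    if (f$space$D != sp$D || f$space$n_fields != sp$n_fields ||
        f$space$order != sp$order || f$space$mesh_hash != sp$mesh_hash) {
      stop("snapshots must share one mesh and function space")
    }
  }
  X <- vapply(fields, function(f) f$coeffs, numeric(sp$n_dofs))
  if (is.null(source_ids)) source_ids <- sprintf("snap-%03d", seq_along(fields))
  structure(list(X = X, source_ids = as.character(source_ids),
                 space = sp, mesh = fields[[1]]$mesh,
                 field_names = fields[[1]]$field_names,
                 target_mesh_hash = sp$mesh_hash),
            class = "grom_snapshots")
}

#' @export
print.grom_snapshots <- function(x, ...) {
  cat(sprintf("<grom_snapshots %d x %d (%d field(s))>\n",
              nrow(x$X), ncol(x$X), x$space$n_fields))
  invisible(x)
}

#' POD reduced basis by singular value decomposition
#'
#' The rank-`d` basis minimizing the Frobenius reconstruction error
#' `||X - U U^T X||_F` is the matrix of the first `d` left singular vectors
#' of `X` (Eckart-Young); the squared reconstruction error equals the sum
#' of the squared discarded singular values.  Column signs are fixed
#' deterministically (the largest-magnitude entry of each basis vector is
#' made positive) for bit-reproducibility.
#'
#' @param snapshots a [build_snapshots()] object (or plain matrix).
#' @param d basis size, `1 <= d <= min(dim(X))`.
#' @return An object of class `grom_basis` with orthonormal `U`
#'   (`n_dofs x d`) and the full singular-value vector `sigma`.
#' @export
pod <- function(snapshots, d) {
  X <- if (inherits(snapshots, "grom_snapshots")) snapshots$X else as.matrix(snapshots)
  S <- min(dim(X))
  if (!(d >= 1 && d <= S)) stop("d must be in [1, ", S, "]")
  sv <- svd(X, nu = d, nv = 0)
  U <- sv$u
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(U = U, sigma = sv$d, d = as.integer(d),
                 space = if (inherits(snapshots, "grom_snapshots")) snapshots$space,
                 mesh = if (inherits(snapshots, "grom_snapshots")) snapshots$mesh,
                 field_names = if (inherits(snapshots, "grom_snapshots"))
                   snapshots$field_names,
                 source_ids = if (inherits(snapshots, "grom_snapshots"))
                   snapshots$source_ids),
            class = "grom_basis")
}

#' @export
print.grom_basis <- function(x, ...) {
  cat(sprintf("<grom_basis d=%d of %d dofs; sigma_1=%.3g, sigma_d/sigma_1=%.3g>\n",
              x$d, nrow(x$U), x$sigma[1], x$sigma[x$d] / x$sigma[1]))
  invisible(x)
}

#' Galerkin projection of an assembled system onto a reduced basis
#'
#' `A_rb = U^T A U`, `F_rb = U^T F`; symmetry of `A` is inherited.
#'
#' @param system a `grom_system`.
#' @param basis a [pod()] basis.
#' @return An object of class `grom_reduced_system`; attribute
#'   `projection_time` records the overhead in seconds.
#' @export
project_system <- function(system, basis) {
  if (nrow(basis$U) != nrow(system$A)) {
    stop("basis dimension ", nrow(basis$U), " does not match system dimension ",
         nrow(system$A))
  }
  t0 <- proc.time()[["elapsed"]]
  AU <- as.matrix(system$A %*% basis$U)
  A_rb <- crossprod(basis$U, AU)
  F_rb <- as.numeric(crossprod(basis$U, system$F))
  structure(list(A_rb = A_rb, F_rb = F_rb, basis = basis,
                 projection_time = proc.time()[["elapsed"]] - t0),
            class = "grom_reduced_system")
}

#' Solve a reduced system (dense direct solve)
#'
#' @param rs a [project_system()] result.
#' @return Reduced coefficients with attributes `residual` and
#'   `solve_time`.
#' @export
solve_reduced <- function(rs) {
  t0 <- proc.time()[["elapsed"]]
  u_rb <- tryCatch(solve(rs$A_rb, rs$F_rb), error = function(e) {
    stop("reduced system singular (reciprocal condition estimate ",
         format(rcond(rs$A_rb), digits = 3), "): ", conditionMessage(e))
  })
  res <- sqrt(sum((rs$A_rb %*% u_rb - rs$F_rb)^2)) /
    max(sqrt(sum(rs$F_rb^2)), .Machine$double.eps)
  attr(u_rb, "residual") <- res
  attr(u_rb, "solve_time") <- proc.time()[["elapsed"]] - t0
  u_rb
}

#' Lift reduced coefficients to the full space
#'
#' @param basis a [pod()] basis built from snapshots (carries mesh/space).
#' @param u_rb reduced coefficient vector of length `d`.
#' @return A [fem_field()] on the target mesh.
#' @export
lift <- function(basis, u_rb) {
  stopifnot(length(u_rb) == basis$d)
  coeffs <- as.numeric(basis$U %*% as.numeric(u_rb))
  fem_field(basis$space, basis$mesh, coeffs, basis$field_names)
}

#' Run the reduced-order pipeline on a target system
#'
#' Builds the snapshot matrix, computes the POD basis of size `d`,
#' projects the target full-order operators, solves the reduced system and
#' lifts the solution.  If a full-order reference is given, per-field
#' relative L2 errors are reported.
#'
#' @param system the full-order `grom_system` assembled on the target mesh.
#' @param snapshots a [build_snapshots()] object of mapped snapshots.
#' @param d basis size.
#' @param reference optional full-order [fem_field()] for error reporting.
#' @return A list with `field`, `basis`, `u_rb`, `errors` (per-field
#'   relative L2 or `NULL`), `sigma`, and `timings`.
#' @export
run_grom <- function(system, snapshots, d, reference = NULL) {
  basis <- pod(snapshots, d)
  rs <- project_system(system, basis)
  u_rb <- solve_reduced(rs)
  fld <- lift(basis, u_rb)
  errors <- if (!is.null(reference)) relative_l2(fld, reference, per_field = TRUE)
  list(field = fld, basis = basis, u_rb = as.numeric(u_rb), errors = errors,
       sigma = basis$sigma,
       timings = c(projection = rs$projection_time,
                   reduced_solve = attr(u_rb, "solve_time")))
}
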