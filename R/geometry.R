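#' Geometry parameters for one synthetic subject
#'
#' A subject geometry is an annular "brain slice": the parenchyma is the
#' region between a star-shaped outer (pial) curve
#' \deqn{R(\theta) = R_0 \left(1 + \sum_{k=3}^{8} a_k \cos(k\theta + \psi_k)\right)}
#' centred at the origin, and an elliptic inner (ventricle) curve with
#' semi-axes `vent_axes` centred at `vent_center`.  The iNPH-like subgroup
#' differs only by enlarged ventricle axes, mirroring ventriculomegaly as the
#' defining geometric feature of that condition.
#'
#' @param subject_id character subject identifier.
#' @param group `"healthy"` or `"inph"`.
#' @param R0 base outer radius in mm.
#' @param fold_amps numeric vector of Fourier fold amplitudes `a_k`,
#'   `k = 3..8` (dimensionless); must satisfy `sum(abs(fold_amps)) < 0.3` so
#'   the outer curve stays star-shaped about the origin.
#' @param fold_phases fold phases `psi_k` in radians, same length as
#'   `fold_amps`.
#' @param vent_center ventricle centre (x, y) in mm.
#' @param vent_axes ventricle semi-axes (a, b) in mm, both positive.
#' @param seed integer per-subject seed recorded for provenance.
#' @return An object of class `grom_geometry`.
#' @export
geometry_params <- function(subject_id, group = c("healthy", "inph"),
                            R0, fold_amps, fold_phases,
                            vent_center = c(0, 0), vent_axes, seed = NA_integer_) {
  group <- match.arg(group)
  stopifnot(is.numeric(R0), R0 > 0,
            length(fold_amps) == length(fold_phases),
            length(vent_center) == 2, length(vent_axes) == 2,
            all(vent_axes > 0))
  if (sum(abs(fold_amps)) >= 0.3) {
    stop("sum(|a_k|) must be < 0.3 to keep the outer boundary star-shaped")
  }
  p <- structure(list(
    subject_id = as.character(subject_id), group = group,
    R0 = R0, fold_amps = as.numeric(fold_amps),
    fold_phases = as.numeric(fold_phases),
    vent_center = as.numeric(vent_center), vent_axes = as.numeric(vent_axes),
    seed = as.integer(seed)), class = "grom_geometry")
  chk <- annulus_gap(p)
  if (chk <= 0) {
    stop("degenerate geometry: ventricle touches or crosses the outer boundary (gap ",
         format(chk), " mm)")
  }
  p
}

#' @export
print.grom_geometry <- function(x, ...) {
  cat(sprintf("<grom_geometry %s [%s] R0=%.1f mm vent=(%.1f, %.1f) mm>\n",
              x$subject_id, x$group, x$R0, x$vent_axes[1], x$vent_axes[2]))
  invisible(x)
}

#' Boundary radius of a subject geometry
#'
#' For `which = "outer"`, the polar radius about the origin of the pial
#' curve; for `which = "ventricle"`, the polar radius about `vent_center` of
#' the ventricle ellipse.  Both are smooth and 2*pi-periodic in `theta`.
#'
#' @param params a [geometry_params()] object.
#' @param theta angle(s) in radians.
#' @param which `"outer"` or `"ventricle"`.
#' @return Radii in mm, same length as `theta`.
#' @export
boundary_radius <- function(params, theta, which = c("outer", "ventricle")) {
  which <- match.arg(which)
  if (which == "outer") {
    k <- seq(3, length.out = length(params$fold_amps))
    mod <- rep(1, length(theta))
    for (j in seq_along(k)) {
      mod <- mod + params$fold_amps[j] * cos(k[j] * theta + params$fold_phases[j])
    }
    params$R0 * mod
  } else {
    a <- params$vent_axes[1]; b <- params$vent_axes[2]
    (a * b) / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  }
}

# Outer-curve radius measured along rays from an arbitrary centre c (the
# ventricle centre).  Solves |c + t e_theta| = R(angle(c + t e_theta)) by
# fixed-point iteration; converges fast because |c| << R0 and dR/dtheta is
# bounded by the fold amplitudes.
outer_radius_from <- function(params, theta, center = params$vent_center) {
  e <- cbind(cos(theta), sin(theta))
  ce <- e[, 1] * center[1] + e[, 2] * center[2]
  c2 <- sum(center^2)
  t <- boundary_radius(params, theta, "outer")
  for (it in 1:40) {
    px <- center[1] + t * e[, 1]
    py <- center[2] + t * e[, 2]
    phi <- atan2(py, px)
    R <- boundary_radius(params, phi, "outer")
    tn <- -ce + sqrt(pmax(R^2 - c2 + ce^2, 0))
    if (max(abs(tn - t)) < 1e-12) { t <- tn; break }
    t <- tn
  }
  t
}

# Minimum radial gap between ventricle boundary and outer boundary measured
# about the ventricle centre (dense angular scan).
annulus_gap <- function(params, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  min(outer_radius_from(params, th) - boundary_radius(params, th, "ventricle"))
}

#' Annular coordinates of points
#'
#' Computes, about the ventricle centre, the polar angle `theta`, the radius
#' `r`, the local ventricle radius `r_v(theta)`, the local outer radius
#' `R(theta)` and the normalized annular coordinate
#' `rho = (r - r_v) / (R - r_v)` (0 on the ventricle boundary, 1 on the pial
#' boundary) for a matrix of points.
#'
#' @param params a [geometry_params()] object.
#' @param points n x 2 matrix of world coordinates in mm.
#' @return A list with components `theta`, `r`, `r_v`, `R`, `rho`.
#' @export
annulus_coords <- function(params, points) {
  points <- as_points(points)
  dx <- points[, 1] - params$vent_center[1]
  dy <- points[, 2] - params$vent_center[2]
  theta <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  r_v <- boundary_radius(params, theta, "ventricle")
  R <- outer_radius_from(params, theta)
  list(theta = theta, r = r, r_v = r_v, R = R, rho = (r - r_v) / (R - r_v))
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = FALSE)
  stopifnot(ncol(points) == 2)
  storage.mode(points) <- "double"
  points
}

#' Cohort specification
#'
#' @param n_healthy,n_inph subgroup sizes (total must be at least 2).
#' @param master_seed integer master seed; the cohort is bit-reproducible
#'   given this seed.
#' @param image_shape integer pair, raster grid size.
#' @param voxel_size voxel edge length in mm.
#' @param mesh_h target mesh size in mm.
#' @return An object of class `grom_cohort_spec`.
#' @export
cohort_spec <- function(n_healthy = 28L, n_inph = 12L, master_seed = 1L,
                        image_shape = c(160L, 160L), voxel_size = 1,
                        mesh_h = 1.5) {
  stopifnot(n_healthy >= 0, n_inph >= 0, n_healthy + n_inph >= 2,
            length(image_shape) == 2, all(image_shape > 0),
            voxel_size > 0, mesh_h > 0)
  structure(list(n_healthy = as.integer(n_healthy), n_inph = as.integer(n_inph),
                 master_seed = as.integer(master_seed),
                 image_shape = as.integer(image_shape),
                 voxel_size = voxel_size, mesh_h = mesh_h),
            class = "grom_cohort_spec")
}

draw_subject <- function(subject_id, group, seed) {
  for (attempt in 0:100) {
    s <- seed + attempt
    set.seed(s)
    R0 <- runif(1, 55, 65)
    amps <- runif(6, 0, 0.04)
    phases <- runif(6, 0, 2 * pi)
    center <- runif(2, -3, 3)
    axes <- if (group == "inph") runif(2, 14, 22) else runif(2, 6, 10)
    p <- try(geometry_params(subject_id, group, R0, amps, phases, center, axes,
                             seed = s), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
  stop("could not draw a valid geometry for subject ", subject_id,
       " (group ", group, ", base seed ", seed, ") after 100 attempts")
}

#' Sample a synthetic cohort
#'
#' Draws a reproducible cohort of annular subject geometries: a healthy-like
#' subgroup with ventricle semi-axes U(6, 10) mm and an iNPH-like subgroup
#' with enlarged semi-axes U(14, 22) mm; base outer radius U(55, 65) mm and
#' fold amplitudes U(0, 0.04).  Each subject carries an independent seed
#' derived from the master seed; a topology check (annular gap > 0) triggers
#' a redraw with an incremented seed (at most 100 attempts).
#'
#' @param spec a [cohort_spec()].
#' @return A list of [geometry_params()] objects, healthy subjects first.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "grom_cohort_spec"))
  n <- spec$n_healthy + spec$n_inph
  set.seed(spec$master_seed)
  seeds <- sample.int(.Machine$integer.max - 200L, n)
  groups <- c(rep("healthy", spec$n_healthy), rep("inph", spec$n_inph))
  ids <- sprintf("sub-%03d", seq_len(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- draw_subject(ids[i], groups[i], seeds[i])
  }
  out
}

#' Build a triangular mesh of the annular geometry
#'
#' Constructs a structured conforming triangulation in annular coordinates:
#' `n_theta` spokes and `n_rho` layers between the ventricle and pial curves,
#' each quadrilateral split into two triangles.  Boundary facets are marked
#' `1` (pial, outer) and `2` (ventricle, inner); every boundary facet carries
#' exactly one marker.  The node count scales like area / h^2.
#'
#' @param params a [geometry_params()] object.
#' @param h target mesh size in mm.
#' @return A `grom_mesh` (see [grom_mesh()]).
#' @export
build_mesh <- function(params, h) {
  stopifnot(h > 0)
  th_probe <- seq(0, 2 * pi, length.out = 257)[-257]
  Rp <- outer_radius_from(params, th_probe)
  rv <- boundary_radius(params, th_probe, "ventricle")
  if (min(Rp - rv) <= 0) stop("degenerate boundary for subject ", params$subject_id)
  r_mid <- mean((Rp + rv) / 2)
  thick <- mean(Rp - rv)
  n_theta <- max(12L, as.integer(ceiling(2 * pi * r_mid / h)))
  n_rho <- max(2L, as.integer(ceiling(thick / h)))

  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  Rth <- outer_radius_from(params, theta)
  rvth <- boundary_radius(params, theta, "ventricle")
  rho <- seq(0, 1, length.out = n_rho + 1)

  # node index: (i_rho, j_theta) -> (i_rho - 1) * n_theta + j_theta
  nid <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  nodes <- matrix(0, nrow = (n_rho + 1L) * n_theta, ncol = 2)
  for (i in seq_len(n_rho + 1L)) {
    r <- rvth + rho[i] * (Rth - rvth)
    idx <- ((i - 1L) * n_theta + 1L):(i * n_theta)
    nodes[idx, 1] <- params$vent_center[1] + r * cos(theta)
    nodes[idx, 2] <- params$vent_center[2] + r * sin(theta)
  }
  cells <- matrix(0L, nrow = 2L * n_rho * n_theta, ncol = 3)
  k <- 0L
  for (i in seq_len(n_rho)) {
    j <- seq_len(n_theta)
    a <- nid(i, j); b <- nid(i, j + 1L); cc <- nid(i + 1L, j); d <- nid(i + 1L, j + 1L)
    cells[k + j, ] <- cbind(a, b, d)
    cells[k + n_theta + j, ] <- cbind(a, d, cc)
    k <- k + 2L * n_theta
  }
  # orient all cells counter-clockwise
  ar <- signed_areas(nodes, cells)
  flip <- which(ar < 0)
  if (length(flip)) cells[flip, c(2, 3)] <- cells[flip, c(3, 2)]
  if (any(signed_areas(nodes, cells) <= 0)) {
    stop("meshing failure (degenerate cell) for subject ", params$subject_id,
         ": R0=", format(params$R0), ", vent_axes=",
         paste(format(params$vent_axes), collapse = ","))
  }
  j <- seq_len(n_theta)
  bed_in <- cbind(nid(1L, j), nid(1L, j + 1L))
  bed_out <- cbind(nid(n_rho + 1L, j), nid(n_rho + 1L, j + 1L))
  bedges <- rbind(bed_out, bed_in)
  markers <- c(rep(1L, n_theta), rep(2L, n_theta))
  grom_mesh(nodes, cells, bedges, markers, h = h)
}

#' Rasterize a subject geometry to an intensity image
#'
#' Produces a T1-like intensity image on the cohort grid: zero outside the
#' parenchyma and inside the ventricle; inside the annulus a radial ramp
#' `0.4 + 0.6 * rho` (with `rho` the normalized annular coordinate)
#' modulated by a weak multi-harmonic texture
#' `1 + (0.08 cos(7 theta) + 0.08 sin(4 theta) +
#' 0.06 cos(11 theta + 3 pi rho)) sin(pi rho)` tied to the annular
#' material coordinates.  The ramp gives the registration radial signal
#' away from the edges; the texture emulates internal T1 contrast and
#' anchors the tangential component of the deformation, which a purely
#' radial intensity profile leaves unidentifiable (any sliding along
#' iso-intensity contours would be invisible to an intensity metric).  The
#' texture vanishes at both boundaries, so near-boundary intensities still
#' approach 1.0 (pial) and 0.4 (ventricle).  Because the texture is a
#' function of the material coordinates, the closed-form inter-subject map
#' transports it exactly: the analytic deformation remains the global
#' optimum of intensity matching.  A one-voxel band at each boundary is
#' anti-aliased by linear coverage weighting.
#'
#' @param params a [geometry_params()] object.
#' @param spec a [cohort_spec()]; the image grid is centred at the origin.
#' @return An [image_grid()] object.
#' @export
rasterize <- function(params, spec) {
  nx <- spec$image_shape[1]; ny <- spec$image_shape[2]
  vs <- spec$voxel_size
  origin <- -vs * (c(nx, ny) - 1) / 2
  xs <- origin[1] + (seq_len(nx) - 1) * vs
  ys <- origin[2] + (seq_len(ny) - 1) * vs
  pts <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  ac <- annulus_coords(params, pts)
  # field-of-view check: outer boundary must stay >= 5 voxels inside the grid
  extent <- max(abs(params$vent_center)) + max(boundary_radius(
    params, seq(0, 2 * pi, length.out = 721), "outer"))
  if (extent + 5 * vs > min(abs(origin))) {
    stop("geometry exceeds the image field of view (need >= 5 voxel margin)")
  }
  rho_c <- pmin(pmax(ac$rho, 0), 1)
  tex <- (0.08 * cos(7 * ac$theta) + 0.08 * sin(4 * ac$theta) +
            0.06 * cos(11 * ac$theta + 3 * pi * rho_c)) * sin(pi * rho_c)
  base <- (0.4 + 0.6 * rho_c) * (1 + tex)
  w <- vs  # anti-aliasing band width: one voxel
  a_in <- pmin(pmax((ac$r - ac$r_v) / w + 0.5, 0), 1)
  a_out <- pmin(pmax((ac$R - ac$r) / w + 0.5, 0), 1)
  img <- base * a_in * a_out
  image_grid(matrix(img, nrow = nx, ncol = ny), origin = origin,
             spacing = c(vs, vs),
             description = paste0("synthetic T1-like ", params$subject_id))
}

# Closed-form inter-subject map in annular coordinates: preserves the angle
# about the ventricle centre and the normalized annular coordinate rho; the
# ventricle interior is scaled radially and the exterior is shifted radially,
# so the map is continuous across the two boundaries.
map_points_closed_form <- function(src, dst, points) {
  points <- as_points(points)
  ac <- annulus_coords(src, points)
  th <- ac$theta
  rv_d <- boundary_radius(dst, th, "ventricle")
  R_d <- outer_radius_from(dst, th)
  r_new <- numeric(length(th))
  inside_vent <- ac$r < ac$r_v
  beyond <- ac$r > ac$R
  annul <- !inside_vent & !beyond
  r_new[inside_vent] <- ac$r[inside_vent] * (rv_d[inside_vent] / ac$r_v[inside_vent])
  r_new[annul] <- rv_d[annul] + ac$rho[annul] * (R_d[annul] - rv_d[annul])
  r_new[beyond] <- R_d[beyond] + (ac$r[beyond] - ac$R[beyond])
  cbind(dst$vent_center[1] + r_new * cos(th),
        dst$vent_center[2] + r_new * sin(th))
}

#' Closed-form deformation between two subject geometries
#'
#' Returns the exact annular-coordinate map from subject `src` to subject
#' `dst` as a deformation object usable wherever a sampled displacement field
#' is (mesh deformation, Jacobians, pullback assembly).  This is the ground
#' truth that image registration approximates.
#'
#' @param src,dst [geometry_params()] objects.
#' @return An object of class `grom_analytic_deformation`.
#' @export
analytic_deformation <- function(src, dst) {
  structure(list(src = src, dst = dst), class = "grom_analytic_deformation")
}

#' Sample the closed-form inter-subject map as a displacement field
#'
#' Evaluates the annular-coordinate map from `src` to `dst` at every voxel
#' centre of the `src` image grid and returns the displacement (in mm, world
#' coordinates, identity-plus-displacement convention).
#'
#' @param src,dst [geometry_params()] objects (both annular).
#' @param spec a [cohort_spec()] defining the grid.
#' @param interp interpolation order for later use of the field.
#' @return A [deformation_field()].
#' @export
analytic_map <- function(src, dst, spec, interp = c("linear", "cubic")) {
  interp <- match.arg(interp)
  nx <- spec$image_shape[1]; ny <- spec$image_shape[2]
  vs <- spec$voxel_size
  origin <- -vs * (c(nx, ny) - 1) / 2
  xs <- origin[1] + (seq_len(nx) - 1) * vs
  ys <- origin[2] + (seq_len(ny) - 1) * vs
  pts <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  mapped <- map_points_closed_form(src, dst, pts)
  u <- mapped - pts
  deformation_field(ux = matrix(u[, 1], nx, ny), uy = matrix(u[, 2], nx, ny),
                    origin = origin, spacing = c(vs, vs), interp = interp)
}

#' Write a cohort manifest
#'
#' @param cohort list of [geometry_params()].
#' @param path output JSON path.
#' @param files optional named list of per-subject file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path, files = NULL) {
  entries <- lapply(cohort, function(p) {
    e <- list(subject_id = p$subject_id, group = p$group, seed = p$seed,
              R0 = p$R0, fold_amps = p$fold_amps, fold_phases = p$fold_phases,
              vent_center = p$vent_center, vent_axes = p$vent_axes)
    if (!is.null(files) && !is.null(files[[p$subject_id]])) {
      e$files <- files[[p$subject_id]]
    }
    e
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort manifest written by [write_manifest()]
#'
#' @param path manifest JSON path.
#' @return A list of [geometry_params()].
#' @export
read_manifest <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(entries, function(e) {
    geometry_params(e$subject_id, e$group, e$R0, unlist(e$fold_amps),
                    unlist(e$fold_phases), unlist(e$vent_center),
                    unlist(e$vent_axes), seed = e$seed)
  })
}
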