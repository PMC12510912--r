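#' Simplicial mesh with boundary markers
#'
#' Container for a 2D triangle mesh.  Boundary facets (edges) carry integer
#' markers: `1` = pial (outer) surface, `2` = ventricle (inner) surface.
#'
#' @param nodes N x 2 matrix of node coordinates in mm.
#' @param cells M x 3 integer matrix of triangle connectivity (1-based,
#'   counter-clockwise).
#' @param boundary_edges K x 2 integer matrix of boundary facet node pairs.
#' @param boundary_markers integer vector of length K with values in
#'   `c(1, 2)` (pial, ventricle).
#' @param h characteristic mesh size in mm.
#' @return An object of class `grom_mesh`.
#' @export
grom_mesh <- function(nodes, cells, boundary_edges, boundary_markers, h = NA_real_) {
  nodes <- as_points(nodes)
  cells <- matrix(as.integer(cells), ncol = 3)
  boundary_edges <- matrix(as.integer(boundary_edges), ncol = 2)
  boundary_markers <- as.integer(boundary_markers)
  stopifnot(nrow(boundary_edges) == length(boundary_markers),
            all(boundary_markers %in% c(1L, 2L)),
            max(cells) <= nrow(nodes), min(cells) >= 1L)
  ar <- signed_areas(nodes, cells)
  if (any(ar <= 0)) stop("mesh has ", sum(ar <= 0), " non-positively oriented cells")
  structure(list(nodes = nodes, cells = cells,
                 boundary_edges = boundary_edges,
                 boundary_markers = boundary_markers, h = h),
            class = "grom_mesh")
}

#' @export
print.grom_mesh <- function(x, ...) {
  cat(sprintf("<grom_mesh %d nodes, %d cells, %d boundary facets (h=%s mm)>\n",
              nrow(x$nodes), nrow(x$cells), nrow(x$boundary_edges),
              format(x$h)), sep = "")
  invisible(x)
}

signed_areas <- function(nodes, cells) {
  x1 <- nodes[cells[, 1], 1]; y1 <- nodes[cells[, 1], 2]
  x2 <- nodes[cells[, 2], 1]; y2 <- nodes[cells[, 2], 2]
  x3 <- nodes[cells[, 3], 1]; y3 <- nodes[cells[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' Total mesh area
#' @param mesh a [grom_mesh()].
#' @return Sum of cell areas in mm^2.
#' @export
mesh_area <- function(mesh) sum(abs(signed_areas(mesh$nodes, mesh$cells)))

#' Length of a marked boundary
#' @param mesh a [grom_mesh()].
#' @param marker boundary marker (1 = pial, 2 = ventricle); `NULL` for all.
#' @return Total length in mm of the marked facets.
#' @export
boundary_length <- function(mesh, marker = NULL) {
  sel <- if (is.null(marker)) rep(TRUE, nrow(mesh$boundary_edges)) else
    mesh$boundary_markers == marker
  e <- mesh$boundary_edges[sel, , drop = FALSE]
  d <- mesh$nodes[e[, 1], , drop = FALSE] - mesh$nodes[e[, 2], , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# cheap structural hash used to check that two fields share a mesh
mesh_hash <- function(mesh) {
  sprintf("%d-%d-%.6e-%.6e", nrow(mesh$nodes), nrow(mesh$cells),
          sum(mesh$nodes), sum(mesh$nodes[, 1] * seq_len(nrow(mesh$nodes))))
}

#' Structured rectangle mesh
#'
#' Uniform triangulation of `[0, Lx] x [0, Ly]`; useful for verification
#' studies on an exactly represented polygonal domain.  The whole boundary is
#' marked pial (1) unless `split_markers` is `TRUE`, in which case the left
#' edge is marked ventricle (2).
#'
#' @param nx,ny number of cells per direction.
#' @param Lx,Ly side lengths in mm.
#' @param split_markers mark the left edge as ventricle.
#' @return A [grom_mesh()].
#' @export
mesh_rectangle <- function(nx, ny, Lx = 1, Ly = 1, split_markers = FALSE) {
  xs <- seq(0, Lx, length.out = nx + 1)
  ys <- seq(0, Ly, length.out = ny + 1)
  nodes <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  cells <- matrix(0L, 2L * nx * ny, 3)
  k <- 0L
  for (j in seq_len(ny)) {
    i <- seq_len(nx)
    a <- nid(i, j); b <- nid(i + 1L, j); cc <- nid(i, j + 1L); d <- nid(i + 1L, j + 1L)
    cells[k + i, ] <- cbind(a, b, d)
    cells[k + nx + i, ] <- cbind(a, d, cc)
    k <- k + 2L * nx
  }
  i <- seq_len(nx); j <- seq_len(ny)
  bottom <- cbind(nid(i, 1L), nid(i + 1L, 1L))
  top <- cbind(nid(i, ny + 1L), nid(i + 1L, ny + 1L))
  left <- cbind(nid(1L, j), nid(1L, j + 1L))
  right <- cbind(nid(nx + 1L, j), nid(nx + 1L, j + 1L))
  bedges <- rbind(bottom, right, top, left)
  markers <- rep(1L, nrow(bedges))
  if (split_markers) markers[(nrow(bedges) - ny + 1L):nrow(bedges)] <- 2L
  grom_mesh(nodes, cells, bedges, markers, h = max(Lx / nx, Ly / ny))
}

#' Write a mesh in Gmsh MSH 4.1 ASCII format
#'
#' Boundary facets are written as 1D line elements in physical groups
#' `pial` (1) and `ventricle` (2); triangles in physical group `domain` (3).
#'
#' @param mesh a [grom_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w("3")
  w("1 1 \"pial\""); w("1 2 \"ventricle\""); w("2 3 \"domain\"")
  w("$EndPhysicalNames")
  n <- nrow(mesh$nodes)
  w("$Nodes")
  w("1 %d 1 %d", n, n)
  w("2 1 0 %d", n)
  writeLines(as.character(seq_len(n)), con)
  writeLines(sprintf("%.16g %.16g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  w("$EndNodes")
  e1 <- mesh$boundary_edges[mesh$boundary_markers == 1L, , drop = FALSE]
  e2 <- mesh$boundary_edges[mesh$boundary_markers == 2L, , drop = FALSE]
  m <- nrow(mesh$cells)
  ne <- nrow(e1) + nrow(e2) + m
  w("$Elements")
  w("3 %d 1 %d", ne, ne)
  id <- 0L
  w("1 1 1 %d", nrow(e1))
  for (k in seq_len(nrow(e1))) { id <- id + 1L; w("%d %d %d", id, e1[k, 1], e1[k, 2]) }
  w("1 2 1 %d", nrow(e2))
  for (k in seq_len(nrow(e2))) { id <- id + 1L; w("%d %d %d", id, e2[k, 1], e2[k, 2]) }
  w("2 3 2 %d", m)
  writeLines(sprintf("%d %d %d %d", id + seq_len(m), mesh$cells[, 1],
                     mesh$cells[, 2], mesh$cells[, 3]), con)
  w("$EndElements")
  invisible(path)
}

#' Write a mesh (optionally with point data) as ASCII VTU
#'
#' @param mesh a [grom_mesh()].
#' @param path output file path.
#' @param point_data optional named list of numeric vectors (one value per
#'   mesh node).
#' @return `path`, invisibly.
#' @export
write_mesh_vtu <- function(mesh, path, point_data = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$cells)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  if (!is.null(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      stopifnot(length(v) == n)
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(paste(format(v, digits = 12), collapse = " "), con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  # boundary marker as cell data on triangles: 0 interior (facet markers are
  # on edges; triangles adjacent to a marked edge inherit its marker)
  cd <- integer(m)
  for (mk in c(1L, 2L)) {
    bn <- unique(as.vector(mesh$boundary_edges[mesh$boundary_markers == mk, ]))
    touches <- rowSums(matrix(mesh$cells %in% bn, nrow = m)) >= 2
    cd[touches & cd == 0L] <- mk
  }
  w('      <CellData>')
  w('        <DataArray type="Int32" Name="boundary_marker" format="ascii">')
  writeLines(paste(cd, collapse = " "), con)
  w('        </DataArray>')
  w('      </CellData>')
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(sprintf("%.12g %.12g 0", mesh$nodes[, 1], mesh$nodes[, 2]),
                   collapse = " "), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(as.vector(t(mesh$cells)) - 1L, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(3L * seq_len(m), collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(5L, m), collapse = " "), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}
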