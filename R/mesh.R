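#' Triangle surface meshes
#'
#' A `surface_mesh` is a closed, consistently oriented triangle mesh: a
#' numeric `vertices` matrix (n x 3, millimetres) and an integer
#' `triangles` matrix (m x 3, 1-based vertex indices).
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param triangles integer matrix, m x 3, vertex index triples.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  if (min(triangles) < 1L || max(triangles) > nrow(vertices))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Unique undirected edges of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return Integer matrix, E x 2, each row an edge with smaller index first.
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Per-triangle areas
#' @param mesh a `surface_mesh`.
#' @return Numeric vector of triangle areas (mm^2).
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-vertex one-ring areas
#'
#' Each vertex receives one third of the area of every incident triangle.
#' This barycentric share is the area weight used by the equi-volume depth
#' placement.
#'
#' @param mesh a `surface_mesh`.
#' @return Numeric vector of length `nrow(mesh$vertices)`.
#' @export
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh) / 3
  nv <- n_vertices(mesh)
  agg <- rowsum(rep(ta, 3L), group = as.vector(mesh$triangles))
  va <- numeric(nv)
  va[as.integer(rownames(agg))] <- agg[, 1]
  va
}

#' Sparse vertex adjacency matrix
#' @param mesh a `surface_mesh`.
#' @return A symmetric sparse 0/1 `Matrix::sparseMatrix`.
#' @export
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  nv <- n_vertices(mesh)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(nv, nv))
}

#' Midpoint subdivision of a triangle mesh
#'
#' Each refinement iteration inserts one vertex at every edge midpoint and
#' splits each triangle into four, so V' = V + E and F' = 4 F. Data defined
#' on the old vertices are preserved; new vertices interpolate their edge
#' endpoints. No reprojection is applied.
#'
#' @param mesh a `surface_mesh`.
#' @param iterations non-negative integer, number of subdivision passes.
#' @return A refined `surface_mesh`.
#' @export
refine_mesh <- function(mesh, iterations = 1) {
  stopifnot(iterations >= 0)
  for (it in seq_len(iterations)) {
    v <- mesh$vertices
    tr <- mesh$triangles
    e <- mesh_edges(mesh)
    nv <- nrow(v)
    key <- function(i, j) pmin(i, j) * (nv + 1) + pmax(i, j)
    mid_id <- stats::setNames(nv + seq_len(nrow(e)), key(e[, 1], e[, 2]))
    mids <- (v[e[, 1], , drop = FALSE] + v[e[, 2], , drop = FALSE]) / 2
    m12 <- mid_id[as.character(key(tr[, 1], tr[, 2]))]
    m23 <- mid_id[as.character(key(tr[, 2], tr[, 3]))]
    m31 <- mid_id[as.character(key(tr[, 3], tr[, 1]))]
    new_tr <- rbind(
      cbind(tr[, 1], m12, m31),
      cbind(tr[, 2], m23, m12),
      cbind(tr[, 3], m31, m23),
      cbind(m12, m23, m31))
    mesh <- surface_mesh(rbind(v, mids), new_tr)
  }
  mesh
}

#' Icosphere mesh
#'
#' Builds a geodesic sphere by midpoint subdivision of a regular
#' icosahedron, reprojecting every vertex to the requested radius after
#' each pass. With `subdivisions = s` the mesh has `20 * 4^s` faces.
#'
#' @param subdivisions non-negative integer.
#' @param radius sphere radius in mm.
#' @param center numeric length-3 center in mm.
#' @return A `surface_mesh`.
#' @export
icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  tr <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- surface_mesh(v / sqrt(1 + phi^2), tr)
  for (s in seq_len(subdivisions)) {
    mesh <- refine_mesh(mesh, 1)
    nrm <- sqrt(rowSums(mesh$vertices^2))
    mesh$vertices <- mesh$vertices / nrm
  }
  mesh$vertices <- sweep(mesh$vertices * radius, 2, center, `+`)
  mesh
}
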