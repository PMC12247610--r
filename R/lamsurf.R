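#' Equi-volume depth fraction
#'
#' Converts a cumulative volume fraction `alpha` into a distance fraction
#' `rho` along the white-to-pial segment, assuming the local cross-section
#' area varies linearly from the inner (white) one-ring area `a_w` to the
#' outer (pial) one-ring area `a_p`. `rho` solves
#' `a_w * rho + (a_p - a_w) * rho^2 / 2 = alpha * (a_w + a_p) / 2`,
#' which places intermediate surfaces so that each shell between
#' consecutive depths encloses the same tissue volume. When `a_w == a_p`
#' the rule reduces to the equidistant `rho = alpha`.
#'
#' @param a_w inner (white surface) area, > 0. Recycled against `alpha`.
#' @param a_p outer (pial surface) area, > 0. Recycled against `alpha`.
#' @param alpha cumulative volume fraction in `[0, 1]`.
#' @return Distance fraction(s) `rho` in `[0, 1]`, strictly increasing in
#'   `alpha`.
#' @export
equivolume_depth_fraction <- function(a_w, a_p, alpha) {
  if (any(a_w <= 0) || any(a_p <= 0)) stop("areas must be positive")
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  n <- max(length(a_w), length(a_p), length(alpha))
  a_w <- rep_len(a_w, n); a_p <- rep_len(a_p, n); alpha <- rep_len(alpha, n)
  rho <- alpha
  ne <- abs(a_p - a_w) > .Machine$double.eps * pmax(a_w, a_p)
  if (any(ne)) {
    rho[ne] <- (-a_w[ne] + sqrt((1 - alpha[ne]) * a_w[ne]^2 +
                                  alpha[ne] * a_p[ne]^2)) /
      (a_p[ne] - a_w[ne])
  }
  pmin(pmax(rho, 0), 1)
}

#' Family of equi-volume depth surfaces
#'
#' A `laminar_mesh` holds `n_depths` surfaces sharing one triangulation:
#' `base` carries the topology, `coords` is a vertex x depth x 3 array of
#' coordinates, depth 1 lying on the white-matter side and depth
#' `n_depths` on the pial side.
#'
#' @param base a `surface_mesh` providing the shared topology.
#' @param coords numeric array, vertices x depths x 3, mm.
#' @param depth_fractions cumulative volume fraction per depth.
#' @param rho optional vertex x depth matrix of distance fractions.
#' @return An object of class `laminar_mesh`.
#' @export
laminar_mesh <- function(base, coords, depth_fractions, rho = NULL) {
  stopifnot(inherits(base, "surface_mesh"),
            length(dim(coords)) == 3,
            dim(coords)[1] == nrow(base$vertices),
            dim(coords)[3] == 3,
            dim(coords)[2] == length(depth_fractions))
  structure(list(base = base, coords = coords,
                 n_depths = dim(coords)[2],
                 depth_fractions = depth_fractions, rho = rho),
            class = "laminar_mesh")
}

#' @export
print.laminar_mesh <- function(x, ...) {
  cat(sprintf("<laminar_mesh> %d vertices x %d depths (deep -> superficial)\n",
              dim(x$coords)[1], x$n_depths))
  invisible(x)
}

#' Build equi-volume depth surfaces between white and pial meshes
#'
#' Places `n_depths` intermediate surfaces along each vertex's
#' white-to-pial segment at the equi-volume distance fractions for
#' cumulative volume fractions at bin centers, `alpha_d = (d - 0.5) / D`.
#' Depth 1 is the deepest (white side) sample; depth `D` the most
#' superficial (pial side). Local areas are per-vertex one-ring
#' triangle-area thirds on the white and pial surfaces.
#'
#' @param white,pial `surface_mesh` objects with identical triangulation.
#' @param n_depths number of depth samples (default 18).
#' @return A `laminar_mesh`.
#' @export
build_depth_surfaces <- function(white, pial, n_depths = 18) {
  stopifnot(inherits(white, "surface_mesh"), inherits(pial, "surface_mesh"))
  if (nrow(white$vertices) != nrow(pial$vertices) ||
      !identical(white$triangles, pial$triangles))
    stop("white and pial surfaces must share topology")
  D <- as.integer(n_depths)
  stopifnot(D >= 2)
  nv <- nrow(white$vertices)
  a_w <- vertex_areas(white)
  a_p <- vertex_areas(pial)
  alpha <- (seq_len(D) - 0.5) / D
  rho <- matrix(0, nv, D)
  for (d in seq_len(D))
    rho[, d] <- equivolume_depth_fraction(a_w, a_p, alpha[d])
  seg <- pial$vertices - white$vertices
  coords <- array(0, c(nv, D, 3))
  for (d in seq_len(D))
    coords[, d, ] <- white$vertices + rho[, d] * seg
  laminar_mesh(white, coords, alpha, rho)
}

#' Laminar dataset: values sampled on a family of depth surfaces
#'
#' @param values numeric array, vertices x depths x time (a vertex x depth
#'   matrix is promoted to a single time point).
#' @param mesh the `laminar_mesh` the values live on.
#' @param session optional session identifier.
#' @return An object of class `laminar_dataset`.
#' @export
laminar_dataset <- function(values, mesh, session = NULL) {
  if (length(dim(values)) == 2) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == dim(mesh$coords)[1],
            dim(values)[2] == mesh$n_depths)
  structure(list(values = values, mesh = mesh, session = session),
            class = "laminar_dataset")
}

#' @export
print.laminar_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<laminar_dataset> %d vertices x %d depths x %d time points\n",
              d[1], d[2], d[3]))
  invisible(x)
}

## mm coordinates -> continuous 1-based voxel indices via the inverse affine
mm_to_index <- function(points, affine) {
  inv <- solve(affine)
  t(inv %*% rbind(t(points), 1))[, 1:3, drop = FALSE]
}

## vectorized trilinear interpolation of one 3D grid at continuous indices
trilinear_at <- function(grid, ix) {
  dm <- dim(grid)
  i0 <- floor(ix)
  f <- ix - i0
  out <- numeric(nrow(ix))
  ok <- i0[, 1] >= 1 & i0[, 1] < dm[1] &
        i0[, 2] >= 1 & i0[, 2] < dm[2] &
        i0[, 3] >= 1 & i0[, 3] < dm[3]
  out[!ok] <- NA_real_
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; f <- f[ok, , drop = FALSE]
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- (i0[, 1] + dx) + (i0[, 2] + dy - 1) * dm[1] +
      (i0[, 3] + dz - 1) * dm[1] * dm[2]
    acc <- acc + w * grid[idx]
  }
  out[ok] <- acc
  out
}

## nearest-voxel lookup after conceptual u-fold grid refinement
upsampled_nearest_index <- function(ix, dm, u) {
  q <- round((ix - 0.5) * u + 0.5)
  i <- ceiling(q / u)
  i <- pmin(pmax(i, 1), matrix(dm, nrow(ix), 3, byrow = TRUE))
  i
}

#' Sample a volume series onto laminar surfaces
#'
#' Evaluates each volume of a series at every (vertex, depth) coordinate of
#' a `laminar_mesh`, honoring the volume's affine. `trilinear` (default)
#' interpolates; `upsample5_nearest` reproduces the project-after-5x-
#' upsampling procedure by snapping to the nearest voxel center of a
#' conceptually 5x refined grid. Vertices outside the volume yield `NA`.
#'
#' @param vol a `volume_series`, or a 3D/4D array.
#' @param lmesh a `laminar_mesh` in the same mm frame as the volume.
#' @param mode `"trilinear"` or `"upsample5_nearest"`.
#' @param affine 4 x 4 voxel-index (1-based) to mm matrix; required when
#'   `vol` is a bare array.
#' @return A `laminar_dataset` (vertices x depths x time).
#' @export
sample_volume_to_surface <- function(vol, lmesh,
                                     mode = c("trilinear", "upsample5_nearest"),
                                     affine = NULL) {
  mode <- match.arg(mode)
  if (inherits(vol, "volume_series")) {
    data <- vol$data; affine <- vol$affine
  } else {
    data <- vol
    if (is.null(affine)) stop("affine required for bare arrays")
  }
  if (length(dim(data)) == 3) data <- array(data, c(dim(data), 1L))
  dm <- dim(data)
  nt <- dm[4]
  nv <- dim(lmesh$coords)[1]
  D <- lmesh$n_depths
  pts <- matrix(aperm(lmesh$coords, c(1, 2, 3)), nv * D, 3)
  ix <- mm_to_index(pts, affine)
  out <- array(NA_real_, c(nv, D, nt))
  if (mode == "trilinear") {
    for (t in seq_len(nt))
      out[, , t] <- trilinear_at(data[, , , t], ix)
  } else {
    i <- upsampled_nearest_index(ix, dm[1:3], 5L)
    flat <- i[, 1] + (i[, 2] - 1) * dm[1] + (i[, 3] - 1) * dm[1] * dm[2]
    nxyz <- prod(dm[1:3])
    for (t in seq_len(nt))
      out[, , t] <- data[flat + (t - 1) * nxyz]
  }
  n_missing <- sum(is.na(out[, , 1]))
  if (n_missing > 0)
    message(sprintf("sample_volume_to_surface: %d of %d vertex-depth points outside volume",
                    n_missing, nv * D))
  laminar_dataset(out, lmesh)
}

#' Surface smoothing within each cortical depth
#'
#' Iterated neighbor-weighted (discrete heat kernel) smoothing applied to
#' each depth surface independently; no signal is exchanged between
#' depths. The kernel width is calibrated per depth from the mean squared
#' edge length so that the equivalent Gaussian kernel has
#' `sigma = fwhm / 2.3548`.
#'
#' @param data a `laminar_dataset`.
#' @param fwhm kernel full width at half maximum in mm; 0 is the identity.
#' @return A smoothed `laminar_dataset`.
#' @export
smooth_within_depth <- function(data, fwhm = 3) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(data)
  mesh <- data$mesh
  e <- mesh_edges(mesh$base)
  nv <- dim(mesh$coords)[1]
  A <- vertex_adjacency(mesh$base)
  deg <- Matrix::rowSums(A)
  W <- A / deg
  sigma2 <- (fwhm / 2.3548)^2
  vals <- data$values
  for (d in seq_len(mesh$n_depths)) {
    vd <- mesh$coords[, d, ]
    e2 <- rowSums((vd[e[, 1], , drop = FALSE] - vd[e[, 2], , drop = FALSE])^2)
    ebar2 <- mean(e2)
    # random-walk step variance is lambda * ebar2; match total 2 sigma^2
    total <- 2 * sigma2 / ebar2
    m <- max(1L, ceiling(total / 0.75))
    lambda <- total / m
    x <- vals[, d, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    for (it in seq_len(m))
      x <- (1 - lambda) * x + lambda * as.matrix(W %*% x)
    vals[, d, ] <- x
  }
  laminar_dataset(vals, mesh, data$session)
}

#' Surface registration map
#'
#' A sparse correspondence from an individual surface to a template: each
#' template vertex is a convex combination of individual vertices. One map
#' is reused at every cortical depth, so registration never mixes depths.
#'
#' @param i integer template vertex indices.
#' @param j integer individual (source) vertex indices.
#' @param w nonnegative weights; rows are renormalized to sum to 1 when
#'   they deviate by more than 1e-6 (with a warning).
#' @param n_template,n_source vertex counts.
#' @return An object of class `registration_map` wrapping a sparse matrix.
#' @export
registration_map <- function(i, j, w, n_template, n_source) {
  M <- Matrix::sparseMatrix(i = i, j = j, x = w,
                            dims = c(n_template, n_source))
  rs <- Matrix::rowSums(M)
  if (any(abs(rs - 1) > 1e-6)) {
    warning("registration weights renormalized to sum to 1")
    M <- M / rs
  }
  structure(list(matrix = M), class = "registration_map")
}

#' Identity registration map
#' @param n vertex count.
#' @return A `registration_map`.
#' @export
identity_registration <- function(n) {
  registration_map(seq_len(n), seq_len(n), rep(1, n), n, n)
}

#' Apply a registration map depth-wise
#'
#' Applies the same vertex correspondence at every cortical depth
#' (block-diagonal over depths): data at depth d on the individual surface
#' map only to depth d on the template.
#'
#' @param map a `registration_map`.
#' @param data a `laminar_dataset` on the individual mesh.
#' @param template_mesh optional `laminar_mesh` for the output.
#' @return A `laminar_dataset` on the template.
#' @export
apply_registration <- function(map, data, template_mesh = NULL) {
  M <- map$matrix
  vals <- data$values
  if (ncol(M) != dim(vals)[1]) stop("registration map does not match data mesh")
  D <- dim(vals)[2]; nt <- dim(vals)[3]
  out <- array(0, c(nrow(M), D, nt))
  for (d in seq_len(D))
    out[, d, ] <- as.matrix(M %*% matrix(vals[, d, ], ncol = nt))
  mesh <- if (is.null(template_mesh)) data$mesh else template_mesh
  structure(list(values = out, mesh = mesh, session = data$session),
            class = "laminar_dataset")
}
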