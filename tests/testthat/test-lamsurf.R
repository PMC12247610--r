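test_that("equi-volume depth fraction: boundaries, limits, analytic example", {
  expect_equal(equivolume_depth_fraction(1, 2, 0), 0)
  expect_equal(equivolume_depth_fraction(1, 2, 1), 1)
  expect_equal(equivolume_depth_fraction(3, 3, 0.37), 0.37)
  # a_w = 1, a_p = 2, alpha = 0.5 -> rho = sqrt(2.5) - 1
  expect_equal(equivolume_depth_fraction(1, 2, 0.5), sqrt(2.5) - 1,
               tolerance = 1e-12)
  expect_equal(round(equivolume_depth_fraction(1, 2, 0.5), 5), 0.58114)
  # strictly increasing in alpha
  rho <- equivolume_depth_fraction(1, 4, seq(0, 1, 0.05))
  expect_true(all(diff(rho) > 0))
  expect_error(equivolume_depth_fraction(-1, 2, 0.5), "positive")
  expect_error(equivolume_depth_fraction(1, 2, 1.5), "alpha")
})

test_that("depth surfaces lie strictly between white and pial, ordered outward", {
  lmesh <- small_lmesh(n_depths = 2, subdiv = 2, r_white = 10, r_pial = 12.5)
  r1 <- sqrt(rowSums(lmesh$coords[, 1, ]^2))
  r2 <- sqrt(rowSums(lmesh$coords[, 2, ]^2))
  expect_true(all(r1 > 10 & r1 < 12.5))
  expect_true(all(r2 > 10 & r2 < 12.5))
  expect_true(all(r2 > r1))
  expect_error(build_depth_surfaces(icosphere(1), icosphere(2)),
               "share topology")
})

test_that("flat parallel patches with equal areas give equidistant bin centers", {
  g <- expand.grid(x = 0:4, y = 0:4)
  nv <- nrow(g)
  id <- function(x, y) x + 5 * y + 1
  tr <- NULL
  for (x in 0:3) for (y in 0:3) {
    tr <- rbind(tr,
                c(id(x, y), id(x + 1, y), id(x + 1, y + 1)),
                c(id(x, y), id(x + 1, y + 1), id(x, y + 1)))
  }
  white <- surface_mesh(cbind(g$x, g$y, 0), tr)
  pial <- surface_mesh(cbind(g$x, g$y, 2), tr)
  lmesh <- build_depth_surfaces(white, pial, n_depths = 4)
  for (d in 1:4) {
    alpha_d <- (d - 0.5) / 4
    expect_equal(lmesh$coords[, d, 3], rep(2 * alpha_d, nv))
  }
})

test_that("volume-to-surface sampling: constants, linear fields, nearest voxel centers", {
  lmesh <- small_lmesh(n_depths = 3, subdiv = 1, r_white = 4, r_pial = 6)
  dims <- c(20, 20, 20)
  affine <- centered_affine(dims, c(1, 1, 1))

  # constant volume -> constant dataset
  out_c <- suppressMessages(sample_volume_to_surface(
    array(7, dims), lmesh, affine = affine))
  expect_equal(out_c$values[, , 1],
               matrix(7, dim(lmesh$coords)[1], 3))

  # linear field f(x, y, z) = x: trilinear is exact
  xs <- (seq_len(dims[1])) * 1 - (dims[1] + 1) / 2
  vol <- array(rep(xs, times = prod(dims[2:3])), dims)
  out_l <- suppressMessages(sample_volume_to_surface(vol, lmesh,
                                                     affine = affine))
  for (d in 1:3)
    expect_equal(out_l$values[, d, 1], lmesh$coords[, d, 1],
                 tolerance = 1e-12)

  # vertex exactly at a voxel center, upsampled-nearest mode
  base <- icosphere(0)
  coords <- array(0, c(12, 2, 3))
  centers_mm <- rbind(c(0.5, -1.5, 2.5), c(-3.5, 0.5, 0.5))
  for (d in 1:2) coords[, d, ] <- matrix(centers_mm[d, ], 12, 3,
                                         byrow = TRUE)
  lm2 <- laminar_mesh(base, coords, c(0.25, 0.75))
  vol2 <- array(stats::rnorm(prod(dims)), dims)
  out_n <- suppressMessages(sample_volume_to_surface(
    vol2, lm2, mode = "upsample5_nearest", affine = affine))
  ijk <- cbind(centers_mm, 1) %*% t(solve(affine))
  for (d in 1:2)
    expect_equal(out_n$values[, d, 1],
                 rep(vol2[ijk[d, 1], ijk[d, 2], ijk[d, 3]], 12))

  # vertices outside the volume are missing
  lm_out <- small_lmesh(n_depths = 2, subdiv = 0, r_white = 40, r_pial = 50)
  expect_message(out_o <- sample_volume_to_surface(array(1, dims), lm_out,
                                                   affine = affine),
                 "outside volume")
  expect_true(all(is.na(out_o$values)))
})

test_that("within-depth smoothing: identity cases and kernel calibration", {
  lmesh <- small_lmesh(n_depths = 2, subdiv = 2, r_white = 10, r_pial = 10.1)
  nv <- dim(lmesh$coords)[1]
  vals <- array(stats::rnorm(nv * 2), c(nv, 2, 1))
  ds <- laminar_dataset(vals, lmesh)
  expect_identical(smooth_within_depth(ds, fwhm = 0)$values, vals)
  expect_error(smooth_within_depth(ds, fwhm = -1), "fwhm")

  const <- laminar_dataset(array(3, c(nv, 2, 1)), lmesh)
  sm <- smooth_within_depth(const, fwhm = 3)
  expect_equal(sm$values, array(3, c(nv, 2, 1)), tolerance = 1e-10)

  # delta spread: geodesic full width at half maximum within 25% of 3 mm
  fine <- small_lmesh(n_depths = 2, subdiv = 4, r_white = 10, r_pial = 10.01)
  nvf <- dim(fine$coords)[1]
  delta <- array(0, c(nvf, 2, 1)); delta[1, , 1] <- 1
  smf <- smooth_within_depth(laminar_dataset(delta, fine), fwhm = 3)
  x <- smf$values[, 1, 1]
  p0 <- fine$coords[1, 1, ]
  ang <- acos(pmin(1, (fine$coords[, 1, ] %*% p0) /
                     sqrt(sum(p0^2) * rowSums(fine$coords[, 1, ]^2))))
  gdist <- as.vector(ang) * 10                # geodesic distance in mm
  ord <- order(gdist)
  below <- which(x[ord] < max(x) / 2 & gdist[ord] > 0)[1]
  i2 <- ord[below]; i1 <- ord[max(1, below - 1)]
  # linear interpolation of the half-max crossing radius
  r_half <- gdist[i1] + (gdist[i2] - gdist[i1]) *
    (max(x) / 2 - x[i1]) / (x[i2] - x[i1])
  fwhm_meas <- 2 * r_half
  expect_lt(abs(fwhm_meas - 3) / 3, 0.25)
})

test_that("registration maps: identity, permutation profiles, renormalization", {
  lmesh <- small_lmesh()
  nv <- dim(lmesh$coords)[1]
  vals <- array(stats::rnorm(nv * 6 * 2), c(nv, 6, 2))
  ds <- laminar_dataset(vals, lmesh)

  id <- identity_registration(nv)
  expect_equal(apply_registration(id, ds)$values, vals)

  perm <- sample.int(nv)
  pm <- registration_map(seq_len(nv), perm, rep(1, nv), nv, nv)
  out <- apply_registration(pm, ds)
  # template vertex i receives source vertex perm[i]: laminar profile of
  # every matched vertex is preserved exactly
  expect_equal(out$values, vals[perm, , , drop = FALSE])

  expect_warning(rw <- registration_map(1:2, 1:2, c(2, 0.5), 2, 2),
                 "renormalized")
  expect_equal(Matrix::rowSums(rw$matrix), c(1, 1))

  expect_error(apply_registration(registration_map(1:3, 1:3, rep(1, 3), 3, 3),
                                  ds), "does not match")
})
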