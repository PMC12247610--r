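test_that("motion enorm examples", {
  p <- rbind(rep(0, 6), c(0.3, 0, 0, 0, 0, 0), c(0.6, 0.3, 0, 0, 0, 0))
  en <- motion_enorm(motion_trace(p))
  expect_equal(en, c(0, 0.3, sqrt(0.18)))
  expect_gt(en[3], 0.4)                       # 0.424... censored territory
  # optional head-radius conversion of rotations
  pr <- rbind(rep(0, 6), c(0, 0, 0, 1, 0, 0))
  enr <- motion_enorm(motion_trace(pr, head_radius_mm = 50))
  expect_equal(enr[2], 50 * pi / 180)
})

test_that("censoring drops dummy pairs and errors when nothing survives", {
  pv <- toy_paired(array(1, c(2, 2, 2, 3)))
  mot <- motion_trace(matrix(0, 6, 6))
  cm <- censor(mot, pv, dummy = c(TRUE, TRUE, rep(FALSE, 4)))
  expect_identical(cm$keep, c(FALSE, TRUE, TRUE))
  expect_identical(cm$reasons[[1]], "dummy")
  expect_error(censor(mot, pv, dummy = rep(TRUE, 6)), "all pairs censored")
})

test_that("outlier fraction: constant and polynomial series are never flagged", {
  nt <- 40
  Y <- matrix(3.5, 30, nt)                          # constant series
  expect_equal(outlier_fraction(Y), rep(0, nt))

  tt <- seq_len(nt)
  P <- cbind(1, stats::poly(tt, 5))
  set.seed(2)
  Y5 <- t(P %*% matrix(stats::rnorm(6 * 50), 6, 50))  # pure 5th-order trends
  expect_equal(outlier_fraction(Y5), rep(0, nt))
})

test_that("outlier fraction finds a constructed 20% displacement", {
  set.seed(7)
  nt <- 60; nvox <- 500
  Y <- matrix(stats::rnorm(nvox * nt), nvox, nt)
  madv <- apply(Y, 1, function(r) stats::mad(r, constant = 1))
  hit <- seq_len(nvox %/% 5)                  # 20% of voxels
  Y[hit, 30] <- Y[hit, 30] + 10 * madv[hit]
  f <- outlier_fraction(Y)
  expect_gt(f[30], 0.15)
  expect_lt(f[30], 0.25)
  expect_lt(max(f[-30]), 0.05)
})

test_that("outlier fraction works on volume_series input and respects masks", {
  sess <- noisefree_session()
  brain <- sess$model$masks$gm | sess$model$masks$wm | sess$model$masks$csf
  f <- outlier_fraction(sess$series, mask = brain)
  expect_length(f, dim(sess$series$data)[4])
  expect_true(all(f >= 0 & f <= 1))
})

test_that("nuisance regression projects out its own regressors", {
  set.seed(11)
  dims <- c(5, 5, 5); np <- 30
  mot <- matrix(stats::rnorm(2 * np * 6, sd = 0.05), 2 * np, 6)
  mot <- apply(mot, 2, cumsum)
  motion <- motion_trace(mot)
  pvix <- cbind(nulled = 2 * seq_len(np) - 1, control = 2 * seq_len(np))
  mot_pairs <- (mot[pvix[, 1], ] + mot[pvix[, 2], ]) / 2

  arr <- array(0, c(dims, np))
  wm_mask <- array(FALSE, dims); wm_mask[1, , ] <- TRUE
  csf_mask <- array(FALSE, dims); csf_mask[5, , ] <- TRUE
  for (t in seq_len(np)) {
    v <- array(5 + mot_pairs[t, 1], dims)     # motion regressor + constant
    v[wm_mask] <- 2                           # constant local WM signal
    v[csf_mask] <- 3                          # constant CSF signal
    arr[, , , t] <- v
  }
  pv <- paired_series(arr, arr, 6.082, pvix,
                      centered_affine(dims, c(1, 1, 1)), c(1, 1, 1))
  mask <- array(FALSE, dims); mask[3, , ] <- TRUE
  rn <- suppressWarnings(regress_nuisance(pv, motion, csf_mask, wm_mask,
                                          mask = mask))
  R <- matrix(rn$data, prod(dims), np)[as.vector(mask), ]
  expect_lt(max(abs(R)), 1e-8)
})

test_that("a series orthogonal to the design is only demeaned and scaled", {
  set.seed(12)
  dims <- c(5, 5, 5); np <- 30
  motion <- motion_trace(matrix(stats::rnorm(2 * np * 6, sd = 0.01),
                                2 * np, 6))
  pvix <- cbind(nulled = 2 * seq_len(np) - 1, control = 2 * seq_len(np))
  mot_pairs <- (motion$params[pvix[, 1], ] + motion$params[pvix[, 2], ]) / 2
  X <- cbind(1, stats::poly(seq_len(np), 5), mot_pairs,
             rbind(rep(0, 6), diff(mot_pairs)))
  Q <- qr.Q(qr(X))
  e <- stats::rnorm(np)
  e <- e - Q %*% crossprod(Q, e)              # orthogonal to the design
  mu <- 4
  y <- as.vector(mu + e)

  arr <- array(0, c(dims, np))
  wm_mask <- array(FALSE, dims); wm_mask[1, , ] <- TRUE
  csf_mask <- array(FALSE, dims); csf_mask[5, , ] <- TRUE
  for (t in seq_len(np)) {
    v <- array(y[t], dims)
    v[wm_mask] <- 2
    v[csf_mask] <- 3
    arr[, , , t] <- v
  }
  pv <- paired_series(arr, arr, 6.082, pvix,
                      centered_affine(dims, c(1, 1, 1)), c(1, 1, 1))
  mask <- array(FALSE, dims); mask[3, 3, 3] <- TRUE
  rn <- suppressWarnings(regress_nuisance(pv, motion, csf_mask, wm_mask,
                                          mask = mask))
  got <- rn$data[3, 3, 3, ]
  expect_equal(got, as.vector(e) / mu, tolerance = 1e-8)
})

test_that("a planted CSF component is recovered and removed", {
  set.seed(13)
  dims <- c(5, 5, 5); np <- 40
  motion <- motion_trace(matrix(0, 2 * np, 6))
  pvix <- cbind(nulled = 2 * seq_len(np) - 1, control = 2 * seq_len(np))
  csf_sig <- stats::rnorm(np)
  z <- stats::rnorm(np)                       # voxel-specific component,
  Xc <- cbind(1, stats::poly(seq_len(np), 5), csf_sig)  # orthogonal to the
  Qc <- qr.Q(qr(Xc))                          # whole shared design
  z <- z - Qc %*% crossprod(Qc, z)
  arr <- array(0, c(dims, np))
  wm_mask <- array(FALSE, dims); wm_mask[1, , ] <- TRUE
  csf_mask <- array(FALSE, dims); csf_mask[5, , ] <- TRUE
  for (t in seq_len(np)) {
    v <- array(10 + 1.0 * csf_sig[t] + z[t], dims)  # coupling exactly 1.0
    v[wm_mask] <- 2
    v[csf_mask] <- csf_sig[t]
    arr[, , , t] <- v
  }
  pv <- paired_series(arr, arr, 6.082, pvix,
                      centered_affine(dims, c(1, 1, 1)), c(1, 1, 1))
  mask <- array(FALSE, dims); mask[3, 3, 3] <- TRUE
  rn <- suppressWarnings(regress_nuisance(pv, motion, csf_mask, wm_mask,
                                          mask = mask))
  # recovered coupling from the shared design
  y <- arr[3, 3, 3, ]
  beta <- qr.coef(qr(rn$design), y)
  expect_lt(abs(beta[["csf"]] - 1.0), 1e-6)
  r <- rn$data[3, 3, 3, ]
  expect_gt(stats::sd(r), 0)
  expect_lt(abs(stats::cor(r, csf_sig)), 1e-6)
})

test_that("local white-matter regressor averages the sphere and falls back globally", {
  dims <- c(8, 8, 8)
  wm <- array(FALSE, dims); wm[1:2, , ] <- TRUE
  data <- array(100, c(dims, 2))             # non-WM voxels must not leak in
  d1 <- array(100, dims); d1[wm] <- 3
  d2 <- array(100, dims); d2[wm] <- 5
  data[, , , 1] <- d1; data[, , , 2] <- d2   # constant WM signal per volume
  w <- local_wm_regressor(data, wm, radius_mm = 3, voxel_size = c(1, 1, 1))
  expect_equal(w[1, 4, 4, 1], 3, tolerance = 1e-6)
  expect_equal(w[1, 4, 4, 2], 5, tolerance = 1e-6)
  # far corner has no WM within 3 mm: global mean fallback
  expect_equal(w[8, 8, 8, 1], 3, tolerance = 1e-6)
})

test_that("regress_evoked removes the regressor inside the region only", {
  lmesh <- small_lmesh()
  nv <- dim(lmesh$coords)[1]
  nt <- 20
  ev <- stats::rnorm(nt)
  vals <- array(0, c(nv, 6, nt))
  for (v in seq_len(nv)) for (d in 1:6) vals[v, d, ] <- 2 * ev + 1
  region <- rep(FALSE, nv); region[1:10] <- TRUE
  out <- regress_evoked(laminar_dataset(vals, lmesh), ev, region)
  expect_lt(max(abs(out$values[1:10, , ])), 1e-10)
  expect_identical(out$values[11:nv, , ], vals[11:nv, , ])

  # zero-variance regressor is a no-op with a warning
  expect_warning(out0 <- regress_evoked(laminar_dataset(vals, lmesh),
                                        rep(1, nt), region), "zero variance")
  expect_identical(out0$values, vals)

  # empty mask is the identity
  out_e <- regress_evoked(laminar_dataset(vals, lmesh), ev, rep(FALSE, nv))
  expect_identical(out_e$values, vals)
})
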