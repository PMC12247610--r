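test_that("fisher z transform: values, clipping, errors", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.5), 5), 0.54931)
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(1), 8.406, tolerance = 1e-4)
  expect_equal(fisher_z(-1), -atanh(1 - 1e-7))
  expect_error(fisher_z(1.5), "> 1")
})

test_that("network FCS: degenerate shared signal, anti-correlation, exclusions", {
  lmesh <- small_lmesh(n_depths = 3)
  nv <- dim(lmesh$coords)[1]
  nt <- 30
  set.seed(4)
  x <- stats::rnorm(nt)
  vals <- array(stats::rnorm(nv * 3 * nt), c(nv, 3, nt))
  for (v in 1:3) for (d in 1:3) vals[v, d, ] <- x      # shared latent
  ds <- laminar_dataset(vals, lmesh)
  net <- rep(FALSE, nv); net[1:3] <- TRUE
  f <- network_fcs(ds, net)
  expect_equal(f$values[1:3, ], matrix(atanh(1 - 1e-7), 3, 3))
  expect_true(all(is.na(f$values[4:nv, ])))

  # source anti-correlated with every target -> no positive z -> FCS 0
  vals2 <- vals
  for (d in 1:3) vals2[2, d, ] <- -x
  f2 <- network_fcs(laminar_dataset(vals2, lmesh), net)
  expect_equal(unname(f2$values[2, ]), rep(0, 3))

  expect_error(network_fcs(ds, rep(FALSE, nv)), "empty")
  expect_error(network_fcs(ds, net, censor_keep = c(rep(TRUE, 4),
                                                    rep(FALSE, nt - 4))),
               "fewer than 8")
})

test_that("network FCS excludes all depths of the source vertex", {
  lmesh <- small_lmesh(n_depths = 2)
  nv <- dim(lmesh$coords)[1]
  nt <- 40
  set.seed(5)
  vals <- array(stats::rnorm(nv * 2 * nt), c(nv, 2, nt))
  # vertex 1's two depths share a signal; vertex 2 is independent noise.
  # If within-vertex pairs were counted, vertex 1 would get clip-level FCS.
  shared <- stats::rnorm(nt)
  vals[1, 1, ] <- shared
  vals[1, 2, ] <- shared
  net <- rep(FALSE, nv); net[1:2] <- TRUE
  f <- network_fcs(laminar_dataset(vals, lmesh), net)
  expect_lt(max(f$values[1, ]), 1)
})

test_that("planted middle-peak coupling yields FCS argmax at depth 9", {
  res <- noisefree_result()
  sess <- noisefree_session()
  net1 <- sess$model$network_masks[, 1]
  prof <- extract_profile(res$fcs[[1]], net1)
  expect_identical(which.max(prof$mean), 9L)
  # per-vertex argmax concentrates at the planted peak
  peaks <- apply(res$fcs[[1]]$values[net1, ], 1, which.max)
  expect_gte(mean(peaks %in% 8:10), 0.9)
})

test_that("seed FCS: clip level, null theory, input checks", {
  lmesh <- small_lmesh(n_depths = 2)
  nv <- dim(lmesh$coords)[1]
  nt <- 400
  set.seed(6)
  vals <- array(stats::rnorm(nv * 2 * nt), c(nv, 2, nt))
  seed_m <- rep(FALSE, nv); seed_m[1:10] <- TRUE
  targ_m <- rep(FALSE, nv); targ_m[11:40] <- TRUE

  # seed series identical to a target series -> clip-level contribution
  vals[11, 1, ] <- vals[1, 1, ]
  ds <- laminar_dataset(vals, lmesh)
  f <- seed_fcs(ds, seed_m, targ_m)
  expect_gt(f$values[11, 1], 0.3)             # one clipped z among 20

  # independent noise: mean FCS matches the half-normal null mean
  # sqrt(2 / pi) / sqrt(n - 3) within 20%
  vals2 <- array(stats::rnorm(nv * 2 * nt), c(nv, 2, nt))
  f0 <- seed_fcs(laminar_dataset(vals2, lmesh), seed_m, targ_m)
  expected <- sqrt(2 / pi) / sqrt(nt - 3)
  got <- mean(f0$values[targ_m, ])
  expect_lt(abs(got - expected) / expected, 0.2)

  expect_error(seed_fcs(ds, rep(FALSE, nv), targ_m), "empty seed")
  both <- seed_m; both[11] <- TRUE
  expect_error(seed_fcs(ds, both, targ_m), "disjoint")
})

test_that("columnar parcellation: singletons, caps, determinism", {
  lmesh <- small_lmesh(n_depths = 3, subdiv = 2)
  nv <- dim(lmesh$coords)[1]
  p_all <- columnar_parcellation(lmesh, K = nv)
  expect_identical(p_all$labels, seq_len(nv))
  expect_error(columnar_parcellation(lmesh, K = nv + 1), "exceeds")

  p2 <- columnar_parcellation(lmesh, K = 2, seed = 3)
  expect_identical(sort(unique(p2$labels)), 1:2)
  # both nodes contiguous on the mesh
  nb <- laminarfcs:::apply_adj_list(vertex_adjacency(lmesh$base))
  for (lab in 1:2) {
    comp <- laminarfcs:::connected_components(which(p2$labels == lab), nb)
    expect_length(comp, 1L)
  }
  p2b <- columnar_parcellation(lmesh, K = 2, seed = 3)
  expect_identical(p2$labels, p2b$labels)
})

test_that("global hubness: middle-depth sharing, flat null, clip case", {
  lmesh <- small_lmesh(n_depths = 6, subdiv = 2)
  nv <- dim(lmesh$coords)[1]
  nt <- 150
  set.seed(8)
  nodes <- columnar_parcellation(lmesh, K = 8, seed = 1)

  # one region shares a signal with the whole cortex at depth 3 only
  vals <- array(stats::rnorm(nv * 6 * nt), c(nv, 6, nt))
  shared <- stats::rnorm(nt)
  vals[, 3, ] <- vals[, 3, ] + matrix(shared, nv, nt, byrow = TRUE)
  hub <- global_hubness(laminar_dataset(vals, lmesh), nodes)
  prof <- colMeans(hub$values)
  expect_identical(which.max(prof), 3L)

  # independent noise everywhere: hubness near the null mean, flat in depth
  vals0 <- array(stats::rnorm(nv * 6 * nt), c(nv, 6, nt))
  hub0 <- global_hubness(laminar_dataset(vals0, lmesh), nodes,
                         exclude_own = TRUE)
  expected <- sqrt(2 / pi) / sqrt(nt - 3)
  expect_lt(abs(mean(hub0$values) - expected) / expected, 0.2)
  df <- data.frame(h = as.vector(hub0$values),
                   d = rep(seq_len(6), each = nv))
  fit <- summary(stats::lm(h ~ d, data = df))
  expect_gt(fit$coefficients["d", "Pr(>|t|)"], 0.01)

  # K = 1 with node series equal to the vertex series -> clip-level hubness
  lm1 <- small_lmesh(n_depths = 2, subdiv = 0)
  nv1 <- dim(lm1$coords)[1]
  x <- stats::rnorm(50)
  same <- array(rep(x, each = nv1 * 2), c(nv1, 2, 50))
  n1 <- columnar_parcellation(lm1, K = 1)
  h1 <- global_hubness(laminar_dataset(same, lm1), n1)
  expect_equal(h1$values, matrix(atanh(1 - 1e-7), nv1, 2))

  # empty node errors
  bad <- n1; bad$K <- 2L
  expect_error(global_hubness(laminar_dataset(same, lm1), bad), "empty node")
})

test_that("extract_profile: normalization, SEM arithmetic, constant flag", {
  m1 <- matrix(c(2, 4, 6), 1, 3)
  p <- extract_profile(m1, 1L, normalize = TRUE)
  expect_equal(p$mean, c(0, 0.5, 1))
  expect_equal(p$sem, rep(0, 3))

  # identical sessions -> SEM 0
  p2 <- extract_profile(list(m1, m1), 1L)
  expect_equal(p2$sem, rep(0, 3))
  expect_identical(p2$n[1], 2L)

  # two sessions [0,1] and [1,0] per depth -> mean 0.5, SEM 0.5
  a <- matrix(c(0, 1), 1, 2); b <- matrix(c(1, 0), 1, 2)
  p3 <- extract_profile(list(a, b), 1L)
  expect_equal(p3$mean, c(0.5, 0.5))
  expect_equal(p3$sem, c(0.5, 0.5))

  expect_warning(pc <- extract_profile(matrix(5, 1, 3), 1L, normalize = TRUE),
                 "constant profile")
  expect_equal(pc$mean, rep(0.5, 3))
  expect_error(extract_profile(m1, integer(0)), "empty")
})
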