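#' Configuration for a synthetic laminar fMRI session
#'
#' Defines the geometry, acquisition timing, planted connectivity
#' structure, and noise of a simulated interleaved blood-nulled/control
#' session. The defaults emulate the study conditions the pipeline is
#' designed for: a volume TR of 6.082 s (effective TR 12.164 s after
#' pairing), 18 equi-volume cortical depths, two planted networks with a
#' middle-peak (feedforward-like) and a superficial-peak (feedback-like)
#' laminar coupling profile, a multiplicative BOLD factor whose amplitude
#' grows toward the pial surface (draining-vein bias), slow drift, motion
#' with occasional spikes, and two leading dummy volumes.
#'
#' @param grid_shape voxels per axis (default `c(44, 44, 44)`).
#' @param voxel_size voxel edge in mm (default 0.7). Together with the
#'   default thickness this gives roughly 3.6 voxels across the cortical
#'   ribbon, enough depth resolution for laminar profile recovery.
#' @param n_vertices target mesh size; the smallest icosphere with at least
#'   this many vertices is used (default 642).
#' @param n_depths cortical depth samples (default 18).
#' @param thickness_range cortical thickness min/max in mm (default
#'   `c(2, 3)`).
#' @param white_radius white-surface radius in mm (default 10).
#' @param volume_tr volume TR in seconds (default 6.082).
#' @param te echo time in seconds, metadata only (default 0.020).
#' @param n_pairs usable nulled/control pairs (default 60); two dummy
#'   volumes are prepended.
#' @param networks list of network specs; each a list with `name`, `center`
#'   (unit direction), `angular_radius` (radians), `profile` (one of
#'   `"middle-peak"`, `"superficial-peak"`, `"double-bump"`, `"flat"`),
#'   `amplitude` (peak CBV coupling, fraction of baseline), `latent`
#'   (latent-signal id; networks sharing an id share a driver).
#' @param vein_bias_slope relative increase of the BOLD gain from the
#'   deepest to the most superficial depth (default 1.5).
#' @param bold_amplitude BOLD signal-change amplitude at the deepest depth
#'   (default 0.02).
#' @param vaper_baseline steady blood-suppression fraction the planted CBV
#'   fluctuations ride on (default 0.05).
#' @param noise_sd multiplicative thermal noise SD, fraction of baseline
#'   (default 0.02).
#' @param vertex_signal_sd amplitude of the spontaneous CBV fluctuation
#'   private to each vertex column, flat across depth (default 0.01).
#'   This vertex-specific physiological signal decorrelates different
#'   columns so that between-column correlations are graded by the planted
#'   coupling amplitude instead of saturating.
#' @param drift_amplitude peak-to-peak slow drift, fraction of baseline
#'   (default 0.02).
#' @param motion_rw_sd per-volume random-walk SD of each motion parameter
#'   (default 0.02 mm / deg).
#' @param motion_spikes integer volume indices receiving a motion spike.
#' @param motion_spike_amp spike amplitude in mm (default 1).
#' @param latent_smooth latent-signal smoothing window in pairs (default 4).
#' @param mt_saturation MT saturation fractions, named `wm` and `gm`
#'   (default 0.3 and 0.1).
#' @param fast_bold if `TRUE`, the BOLD factor fluctuates independently for
#'   the two volumes of a pair, leaving residual contamination in the
#'   contrast (default `FALSE`: slow BOLD, identical within a pair).
#' @param seed integer; fully determines every generated output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(44, 44, 44),
                             voxel_size = 0.7,
                             n_vertices = 642,
                             n_depths = 18,
                             thickness_range = c(2, 3),
                             white_radius = 10,
                             volume_tr = 6.082,
                             te = 0.020,
                             n_pairs = 60,
                             networks = default_networks(),
                             vein_bias_slope = 1.5,
                             bold_amplitude = 0.02,
                             vaper_baseline = 0.05,
                             noise_sd = 0.02,
                             vertex_signal_sd = 0.01,
                             drift_amplitude = 0.02,
                             motion_rw_sd = 0.02,
                             motion_spikes = c(30L, 80L),
                             motion_spike_amp = 1,
                             latent_smooth = 4,
                             mt_saturation = c(wm = 0.3, gm = 0.1),
                             fast_bold = FALSE,
                             seed = 1L) {
  stopifnot(n_depths >= 2, volume_tr > 0, n_pairs >= 4,
            all(thickness_range > 0), diff(thickness_range) >= 0,
            noise_sd >= 0, vein_bias_slope >= 0)
  for (nw in networks)
    if (any(coupling_profile(nw$profile, n_depths) < 0))
      stop("coupling profiles must be nonnegative")
  cfg <- list(grid_shape = as.integer(rep_len(grid_shape, 3)),
              voxel_size = rep_len(voxel_size, 3),
              n_vertices = n_vertices, n_depths = as.integer(n_depths),
              thickness_range = thickness_range,
              white_radius = white_radius,
              volume_tr = volume_tr, te = te, n_pairs = as.integer(n_pairs),
              networks = networks, vein_bias_slope = vein_bias_slope,
              bold_amplitude = bold_amplitude,
              vaper_baseline = vaper_baseline,
              noise_sd = noise_sd, vertex_signal_sd = vertex_signal_sd,
              drift_amplitude = drift_amplitude,
              motion_rw_sd = motion_rw_sd,
              motion_spikes = as.integer(motion_spikes),
              motion_spike_amp = motion_spike_amp,
              latent_smooth = latent_smooth,
              mt_saturation = mt_saturation,
              fast_bold = fast_bold, seed = as.integer(seed))
  structure(cfg, class = "synthetic_config")
}

#' Default planted networks
#'
#' Two antipodal cortical patches: one with a middle-peak (feedforward-like)
#' laminar coupling, one with a superficial-peak (feedback-like) coupling,
#' each driven by its own latent signal. The patch centers lie on the
#' (1,1,1) diagonal, a generic direction with respect to the voxel lattice,
#' so no cortical column is exactly grid-aligned.
#'
#' @return A list of network specifications.
#' @export
default_networks <- function() {
  u <- c(1, 1, 1) / sqrt(3)
  list(
    list(name = "net_middle", center = u, angular_radius = 0.7,
         profile = "middle-peak", amplitude = 0.04, latent = "g1"),
    list(name = "net_superficial", center = -u, angular_radius = 0.7,
         profile = "superficial-peak", amplitude = 0.04, latent = "g2"))
}

#' Laminar coupling profile shapes
#'
#' Nonnegative depth profiles (max 1) used to plant laminar connectivity:
#' `middle-peak` is a Gaussian centered at the middle depth (bin 9 of 18),
#' `superficial-peak` one centered near the pial surface (bin 17 of 18),
#' `double-bump` a mixture peaking at deep and superficial depths, `flat`
#' is constant (used for seed regions).
#'
#' @param type profile name.
#' @param n_depths number of depths.
#' @return Numeric vector of length `n_depths`, values in `[0, 1]`.
#' @export
coupling_profile <- function(type, n_depths = 18) {
  d <- seq_len(n_depths)
  sdw <- n_depths / 9
  switch(type,
    "middle-peak" = exp(-(d - round(n_depths / 2))^2 / (2 * sdw^2)),
    "superficial-peak" = exp(-(d - (n_depths - 1))^2 / (2 * sdw^2)),
    "double-bump" = {
      p <- 0.8 * exp(-(d - round(n_depths * 0.28))^2 / (2 * sdw^2)) +
        exp(-(d - round(n_depths * 0.83))^2 / (2 * sdw^2))
      p / max(p)
    },
    "flat" = rep(1, n_depths),
    stop("unknown coupling profile: ", type))
}

#' Coupling profile evaluated at continuous equi-volume depth fractions
#'
#' Same shapes as [coupling_profile()] but parameterized by the cumulative
#' volume fraction `alpha` in `[0, 1]`, so that voxels are coupled by their
#' exact depth rather than their depth bin (`alpha = (d - 0.5) / D`
#' reproduces the binned profile at bin centers).
#'
#' @param type profile name.
#' @param alpha cumulative volume fraction(s).
#' @param n_depths number of depth bins defining the profile geometry.
#' @return Numeric vector, values in `[0, 1]`.
#' @export
coupling_at_alpha <- function(type, alpha, n_depths = 18) {
  a_of <- function(d) (d - 0.5) / n_depths
  sda <- (n_depths / 9) / n_depths
  switch(type,
    "middle-peak" = exp(-(alpha - a_of(round(n_depths / 2)))^2 / (2 * sda^2)),
    "superficial-peak" = exp(-(alpha - a_of(n_depths - 1))^2 / (2 * sda^2)),
    "double-bump" = {
      p <- 0.8 * exp(-(alpha - a_of(round(n_depths * 0.28)))^2 / (2 * sda^2)) +
        exp(-(alpha - a_of(round(n_depths * 0.83)))^2 / (2 * sda^2))
      p / max(0.8 * 1, 1)
    },
    "flat" = rep(1, length(alpha)),
    stop("unknown coupling profile: ", type))
}

#' Peak depth of a planted coupling profile
#' @param type profile name.
#' @param n_depths number of depths.
#' @return Integer depth index of the profile maximum.
#' @export
profile_peak_depth <- function(type, n_depths = 18) {
  which.max(coupling_profile(type, n_depths))
}

icosphere_subdivisions_for <- function(n_vertices) {
  s <- 0
  while (10 * 4^s + 2 < n_vertices) s <- s + 1
  s
}

#' Synthetic cortical model: geometry, tissue masks, voxel columns
#'
#' Builds a sphere-based cortical ribbon: the white surface is an icosphere
#' of radius `white_radius`, the pial surface lies at a spatially varying
#' thickness along the outward normal, and the 18 equi-volume depth
#' surfaces are placed between them. Every gray-matter voxel is assigned to
#' its nearest vertex column and to an equi-volume depth bin; WM/GM/CSF
#' voxel masks consistent with the surfaces are returned.
#'
#' @param config a `synthetic_config`.
#' @return An object of class `cortical_model` with fields `white`, `pial`,
#'   `lmesh`, `thickness`, `masks` (logical arrays `wm`, `gm`, `csf`),
#'   `voxel_column`, `voxel_depth` (integer arrays, `NA` outside GM),
#'   `affine`, `network_masks` (vertex x network logical matrix), `config`.
#' @export
make_cortical_model <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  subdiv <- icosphere_subdivisions_for(config$n_vertices)
  white <- icosphere(subdiv, radius = config$white_radius)
  dirs <- white$vertices / config$white_radius
  tr <- config$thickness_range
  thickness <- tr[1] + (tr[2] - tr[1]) * (dirs[, 1] + 1) / 2
  pial <- surface_mesh(white$vertices + thickness * dirs, white$triangles)
  max_r <- config$white_radius + max(thickness)
  half_extent <- min(config$grid_shape * config$voxel_size) / 2
  if (max_r + 1.5 + max(config$voxel_size) > half_extent)
    stop("mesh does not fit in the grid with a voxel margin; enlarge grid_shape")
  if (any(thickness <= 0))
    stop("surface offset produces self-intersection; reject config")
  lmesh <- build_depth_surfaces(white, pial, config$n_depths)
  vox <- voxelize_model(white, pial, thickness, config)
  network_masks <- vapply(config$networks, function(nw) {
    ctr <- nw$center / sqrt(sum(nw$center^2))
    as.vector(acos(pmin(pmax(dirs %*% ctr, -1), 1)) <= nw$angular_radius)
  }, logical(nrow(dirs)))
  structure(list(white = white, pial = pial, lmesh = lmesh,
                 thickness = thickness, masks = vox$masks,
                 voxel_column = vox$column, voxel_depth = vox$depth,
                 voxel_alpha = vox$alpha,
                 affine = vox$affine, network_masks = network_masks,
                 config = config),
            class = "cortical_model")
}

#' @export
print.cortical_model <- function(x, ...) {
  cat(sprintf("<cortical_model> %d vertices, %d depths; GM %d / WM %d / CSF %d voxels\n",
              nrow(x$white$vertices), x$config$n_depths,
              sum(x$masks$gm), sum(x$masks$wm), sum(x$masks$csf)))
  invisible(x)
}

## assign voxels to tissue, vertex column and equi-volume depth bin
voxelize_model <- function(white, pial, thickness, config) {
  dims <- config$grid_shape
  vs <- config$voxel_size
  affine <- centered_affine(dims, vs)
  gi <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                    k = seq_len(dims[3]))
  mm <- cbind(gi$i * vs[1], gi$j * vs[2], gi$k * vs[3])
  mm <- sweep(mm, 2, vs * (dims + 1) / 2)
  r <- sqrt(rowSums(mm^2))
  Rw <- config$white_radius
  tmax <- max(thickness)
  csf_th <- 1.5

  wm <- r <= Rw
  shell <- r > Rw & r <= Rw + tmax + csf_th
  column <- rep(NA_integer_, nrow(mm))
  # nearest vertex by direction, chunked to bound memory
  dirs_v <- white$vertices / Rw
  sh_idx <- which(shell)
  if (length(sh_idx) > 0) {
    ub <- mm[sh_idx, , drop = FALSE] / r[sh_idx]
    nearest <- integer(length(sh_idx))
    step <- 20000L
    for (s in seq(1, length(sh_idx), by = step)) {
      e <- min(s + step - 1L, length(sh_idx))
      dots <- ub[s:e, , drop = FALSE] %*% t(dirs_v)
      nearest[s:e] <- max.col(dots, ties.method = "first")
    }
    column[sh_idx] <- nearest
  }
  th_vox <- rep(NA_real_, nrow(mm))
  th_vox[sh_idx] <- thickness[column[sh_idx]]
  gm <- shell & r <= Rw + th_vox
  csf <- shell & !gm
  # equi-volume depth bin within the column
  a_w <- vertex_areas(white)
  a_p <- vertex_areas(pial)
  depth <- rep(NA_integer_, nrow(mm))
  alpha_vox <- rep(NA_real_, nrow(mm))
  g_idx <- which(gm)
  if (length(g_idx) > 0) {
    col_g <- column[g_idx]
    tfrac <- (r[g_idx] - Rw) / th_vox[g_idx]
    aw <- a_w[col_g]; ap <- a_p[col_g]
    alpha <- (aw * tfrac + (ap - aw) * tfrac^2 / 2) / ((aw + ap) / 2)
    alpha_vox[g_idx] <- alpha
    depth[g_idx] <- as.integer(pmin(config$n_depths,
                                    pmax(1L, ceiling(alpha * config$n_depths))))
  }
  column[!(gm | csf)] <- NA_integer_   # CSF keeps its column: pial veins
  list(masks = list(wm = array(wm, dims), gm = array(gm, dims),
                    csf = array(csf, dims)),
       column = array(column, dims), depth = array(depth, dims),
       alpha = array(alpha_vox, dims), affine = affine)
}

## smooth standardized latent signal (moving-average filtered white noise)
make_latent <- function(n, window) {
  x <- stats::rnorm(n + 2 * window)
  if (window > 1) x <- stats::filter(x, rep(1 / window, window), sides = 2)
  x <- x[window + seq_len(n)]
  as.numeric(scale(x))
}

#' Simulate an interleaved blood-nulled/control session
#'
#' Generates the raw volume series according to the multiplicative signal
#' model: for each pair t, the control volume is
#' `C = S0 (1 + b) (1 + drift) (1 + noise_C)` and the blood-nulled volume
#' `N = S0 (1 - v) (1 + b) (1 + drift) (1 + noise_N)`, where
#' `v = v0 + sum_n beta[v, d, n] g_n(t) + c_w w_v(t)` is the planted
#' intravascular (CBV) signal riding on the steady suppression baseline
#' `v0` (`w_v` is the spontaneous fluctuation private to the voxel's vertex
#' column, flat across depth), and `b` is a
#' multiplicative BOLD factor whose gain increases monotonically with depth
#' toward the pial surface (draining-vein bias). The BOLD factor and drift
#' are shared by the two volumes of a pair (slow-BOLD assumption) unless
#' `fast_bold` is set; thermal noise is independent per volume. Two dummy
#' volumes lead the run. Motion parameters follow a random walk with
#' spikes; spike volumes also corrupt a fraction of in-brain voxels so the
#' outlier criterion has something to find.
#'
#' @param config a `synthetic_config`.
#' @param model the matching `cortical_model` (built if omitted).
#' @param seed RNG seed override (defaults to `config$seed`).
#' @return A list of class `synthetic_session`: `series` (a
#'   `volume_series`), `motion` (a `motion_trace`), `anat` (list with
#'   `ctrl_mean`, `mt_mean`), `truth` (a `ground_truth`), and `model`.
#' @export
simulate_session <- function(config, model = NULL, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(model)) model <- make_cortical_model(config)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  D <- config$n_depths
  dims <- config$grid_shape
  nxyz <- prod(dims)
  np <- config$n_pairs + 1L              # first pair = dummies
  nvol <- 2L * np

  # latent signals, one per unique latent id
  lat_ids <- unique(vapply(config$networks, `[[`, character(1), "latent"))
  G <- vapply(lat_ids, function(id) make_latent(np, config$latent_smooth),
              numeric(np))
  G <- matrix(G, nrow = np)
  colnames(G) <- lat_ids

  # per-voxel planted CBV signal v and BOLD gain
  gm_idx <- which(as.vector(model$masks$gm))
  col_g <- as.vector(model$voxel_column)[gm_idx]
  dep_g <- as.vector(model$voxel_depth)[gm_idx]
  alpha_g <- as.vector(model$voxel_alpha)[gm_idx]
  v_sig <- matrix(0, length(gm_idx), np)     # planted CBV fluctuation
  b_gain <- numeric(length(gm_idx))
  net_drive <- matrix(0, length(gm_idx), np) # summed latent drive
  truth_peak <- rep(NA_integer_, nrow(model$white$vertices))
  truth_label <- rep(NA_integer_, nrow(model$white$vertices))
  for (ni in seq_along(config$networks)) {
    nw <- config$networks[[ni]]
    beta_d <- nw$amplitude * coupling_profile(nw$profile, D)
    vmask <- model$network_masks[, ni]
    in_net <- vmask[col_g]
    if (!any(in_net)) next
    g <- G[, nw$latent]
    beta_vox <- nw$amplitude * coupling_at_alpha(nw$profile,
                                                 alpha_g[in_net], D)
    v_sig[in_net, ] <- v_sig[in_net, ] + outer(beta_vox, g)
    net_drive[in_net, ] <- net_drive[in_net, ] + outer(rep(1, sum(in_net)), g)
    truth_peak[vmask] <- which.max(beta_d)
    truth_label[vmask] <- switch(nw$profile,
                                 "middle-peak" = 1L,
                                 "superficial-peak" = 2L, NA_integer_)
  }
  # spontaneous CBV fluctuation private to each vertex column (flat in depth)
  if (config$vertex_signal_sd > 0) {
    nv <- nrow(model$white$vertices)
    Wv <- vapply(seq_len(nv), function(i) make_latent(np, config$latent_smooth),
                 numeric(np))                 # np x nv
    v_sig <- v_sig + config$vertex_signal_sd * t(Wv)[col_g, , drop = FALSE]
  }
  slope <- config$vein_bias_slope
  b_gain <- config$bold_amplitude * (1 + slope * alpha_g)

  # pial/CSF voxels over network columns carry the draining-vein BOLD
  # response at full superficial gain (no CBV signal there)
  csf_idx <- which(as.vector(model$masks$csf))
  col_csf <- as.vector(model$voxel_column)[csf_idx]
  csf_drive <- matrix(0, length(csf_idx), np)
  for (ni in seq_along(config$networks)) {
    nw <- config$networks[[ni]]
    in_net <- !is.na(col_csf) & model$network_masks[col_csf, ni]
    if (any(in_net))
      csf_drive[in_net, ] <- csf_drive[in_net, ] +
        outer(rep(1, sum(in_net)), G[, nw$latent])
  }
  b_gain_csf <- config$bold_amplitude * (1 + slope)

  v <- config$vaper_baseline + v_sig
  overshoot <- v >= 0.95
  if (any(overshoot)) {
    warning(sprintf("nulling overshoot at %d voxel-times; clipped", sum(overshoot)))
    v[overshoot] <- 0.95
  }

  # baseline intensities
  S0 <- numeric(nxyz)
  S0[as.vector(model$masks$wm)] <- 800
  S0[gm_idx] <- 1000
  S0[as.vector(model$masks$csf)] <- 1200

  # slow drift, shared within pair
  tt <- seq_len(np) / np
  drift <- config$drift_amplitude *
    (tt - 0.5 + 0.5 * sin(2 * pi * tt)) # smooth, zero-ish mean

  # steady suppression applies to all brain tissue; fluctuations only in GM
  brain_idx <- which(S0 > 0)
  data <- array(0, c(dims, nvol))
  noise_mult <- function(n) 1 + config$noise_sd * stats::rnorm(n)
  for (p in seq_len(np)) {
    b_fac_n <- b_fac_c <- 1 + b_gain * net_drive[, p]
    if (config$fast_bold) {
      jitterb <- config$bold_amplitude * 0.5 * stats::rnorm(length(b_gain))
      b_fac_c <- b_fac_c + jitterb
    }
    common <- (1 + drift[p])
    b_csf <- 1 + b_gain_csf * csf_drive[, p]
    Nvol <- S0
    Nvol[brain_idx] <- Nvol[brain_idx] * (1 - config$vaper_baseline)
    # GM: replace the flat baseline by baseline + planted signal, with BOLD
    Nvol[gm_idx] <- S0[gm_idx] * (1 - v[, p]) * b_fac_n
    Nvol[csf_idx] <- Nvol[csf_idx] * b_csf
    Nvol <- Nvol * common
    Cvol <- S0
    Cvol[gm_idx] <- Cvol[gm_idx] * b_fac_c
    Cvol[csf_idx] <- Cvol[csf_idx] * b_csf
    Cvol <- Cvol * common
    if (config$noise_sd > 0) {
      Nvol <- Nvol * noise_mult(nxyz)
      Cvol <- Cvol * noise_mult(nxyz)
    }
    data[, , , 2 * p - 1] <- Nvol
    data[, , , 2 * p] <- Cvol
  }

  # motion: random walk + spikes; spike volumes also corrupt intensities
  mot <- apply(matrix(stats::rnorm(nvol * 6, sd = config$motion_rw_sd),
                      nvol, 6), 2, cumsum)
  spikes <- config$motion_spikes[config$motion_spikes <= nvol]
  if (length(spikes) > 0) {
    mot[spikes, 1] <- mot[spikes, 1] + config$motion_spike_amp
    brain <- which(S0 > 0)
    for (sv in spikes) {
      hit <- sample(brain, length(brain) %/% 5)
      vol <- data[, , , sv]
      vol[hit] <- vol[hit] * 1.5
      data[, , , sv] <- vol
    }
  }

  schedule <- rep(c("nulled", "control"), np)
  dummy <- c(TRUE, TRUE, rep(FALSE, nvol - 2L))
  series <- volume_series(data, config$voxel_size, config$volume_tr,
                          schedule, dummy, te = config$te,
                          affine = model$affine)

  # MT anatomical pair (means over a short MT run)
  sat <- numeric(nxyz)
  sat[as.vector(model$masks$wm)] <- config$mt_saturation[["wm"]]
  sat[gm_idx] <- config$mt_saturation[["gm"]]
  anat <- list(ctrl_mean = array(S0, dims),
               mt_mean = array(S0 * (1 - sat), dims))

  truth <- structure(list(labels = truth_label, peak_depth = truth_peak,
                          network_masks = model$network_masks,
                          latent_signals = t(G[-1, , drop = FALSE]),
                          drift = drift, v_baseline = config$vaper_baseline,
                          v_signal = v_sig, gm_index = gm_idx,
                          bold_gain = b_gain, net_drive = net_drive),
                     class = "ground_truth")
  structure(list(series = series, motion = motion_trace(mot),
                 anat = anat, truth = truth, model = model, seed = seed),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> seed %d: %d volumes, %d networks\n",
              x$seed, dim(x$series$data)[4], ncol(x$truth$network_masks)))
  invisible(x)
}

## small rotation matrix about an axis
rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s_ * K + (1 - c_) * (K %*% K)
}

#' Generate a group of synthetic sessions with known registration
#'
#' Each session's cortical model is a known deformation of the template: a
#' random vertex re-indexing plus a small rigid rotation. The exact inverse
#' correspondence is returned as that session's `registration_map`, so the
#' planted labels of all sessions agree vertex-wise on the template after
#' registration. With `deform = FALSE` every session uses the template
#' geometry and an identity map.
#'
#' @param config a `synthetic_config`.
#' @param n_sessions number of sessions (>= 2).
#' @param deform apply per-session deformation (default `TRUE`).
#' @param max_rotation maximal rotation angle in radians (default 0.15).
#' @return A list of class `synthetic_group`: `sessions` (list of
#'   `synthetic_session`), `template` (the template `cortical_model`),
#'   `maps` (list of `registration_map`), `truth` (template-space planted
#'   labels and peak depths).
#' @export
make_group <- function(config, n_sessions, deform = TRUE,
                       max_rotation = 0.15) {
  stopifnot(n_sessions >= 2)
  template <- make_cortical_model(config)
  nv <- nrow(template$white$vertices)
  sessions <- vector("list", n_sessions)
  maps <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    sess_seed <- (config$seed + 7919L * s) %% 2147483647L
    old <- .Random.seed_get()
    set.seed(sess_seed)
    if (deform) {
      perm <- sample.int(nv)
      axis <- stats::rnorm(3)
      angle <- stats::runif(1, -max_rotation, max_rotation)
      R <- rotation_about(axis, angle)
    } else {
      perm <- seq_len(nv)
      R <- diag(3)
    }
    .Random.seed_set(old)
    model_s <- deform_model(template, perm, R, config)
    sessions[[s]] <- simulate_session(config, model_s, seed = sess_seed)
    inv <- integer(nv); inv[perm] <- seq_len(nv)
    maps[[s]] <- registration_map(i = seq_len(nv), j = inv,
                                  w = rep(1, nv), nv, nv)
  }
  truth <- list(labels = template_truth_labels(template),
                network_masks = template$network_masks)
  structure(list(sessions = sessions, template = template, maps = maps,
                 truth = truth), class = "synthetic_group")
}

template_truth_labels <- function(model) {
  nv <- nrow(model$white$vertices)
  labels <- rep(NA_integer_, nv)
  for (ni in seq_along(model$config$networks)) {
    nw <- model$config$networks[[ni]]
    lab <- switch(nw$profile, "middle-peak" = 1L,
                  "superficial-peak" = 2L, NA_integer_)
    labels[model$network_masks[, ni]] <- lab
  }
  labels
}

## apply a vertex permutation + rotation to the template model and
## re-voxelize so the session has consistent masks and columns
deform_model <- function(template, perm, R, config) {
  wv <- template$white$vertices[perm, , drop = FALSE] %*% t(R)
  tri <- template$white$triangles
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  tri_new <- matrix(inv[tri], ncol = 3)
  white <- surface_mesh(wv, tri_new)
  thickness <- template$thickness[perm]
  dirs <- wv / config$white_radius
  pial <- surface_mesh(wv + thickness * dirs, tri_new)
  lmesh <- build_depth_surfaces(white, pial, config$n_depths)
  vox <- voxelize_model(white, pial, thickness, config)
  network_masks <- template$network_masks[perm, , drop = FALSE]
  structure(list(white = white, pial = pial, lmesh = lmesh,
                 thickness = thickness, masks = vox$masks,
                 voxel_column = vox$column, voxel_depth = vox$depth,
                 voxel_alpha = vox$alpha,
                 affine = vox$affine, network_masks = network_masks,
                 config = config),
            class = "cortical_model")
}
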