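# Shared fixtures, memoized so expensive synthetic sessions are simulated
# once per test run regardless of which test file first touches them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# Thermal-noise-free configuration: noise_sd = 0 and no motion spikes (spike
# volumes deliberately corrupt voxel intensities, which would break the
# machine-precision contrast identities). Everything else is at defaults,
# including the spontaneous per-column CBV fluctuation.
noisefree_config <- function(...) {
  synthetic_config(noise_sd = 0, motion_spikes = integer(0), ...)
}

default_model <- function() {
  fixture("model_default", make_cortical_model(synthetic_config()))
}

# noise-free session on the default geometry
noisefree_session <- function() {
  fixture("session_nf",
          suppressWarnings(simulate_session(noisefree_config(),
                                            model = default_model())))
}

# full session pipeline on the noise-free session
noisefree_result <- function() {
  fixture("result_nf",
          suppressMessages(suppressWarnings(
            run_session(noisefree_session()))))
}

# small laminar mesh between two concentric icospheres
small_lmesh <- function(n_depths = 6, subdiv = 1, r_white = 10,
                        r_pial = 12) {
  white <- icosphere(subdiv, radius = r_white)
  pial <- surface_mesh(white$vertices * (r_pial / r_white),
                       white$triangles)
  build_depth_surfaces(white, pial, n_depths)
}

# minimal paired_series wrapper for constructed 4D fixtures
toy_paired <- function(vaper, volume_tr = 6.082) {
  np <- dim(vaper)[4]
  paired_series(vaper, vaper, volume_tr,
                pair_volumes = cbind(nulled = 2 * seq_len(np) - 1,
                                     control = 2 * seq_len(np)),
                affine = centered_affine(dim(vaper)[1:3], c(1, 1, 1)),
                voxel_size = c(1, 1, 1))
}
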