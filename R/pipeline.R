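#' Pipeline parameters
#'
#' All numeric defaults of the session and group pipelines in one place:
#' motion-censoring threshold 0.4 mm, outlier fraction 0.10, drift
#' polynomial order 5, local white-matter radius 15 mm, within-depth
#' smoothing FWHM 3 mm, 18 cortical depths, k = 2 profile clusters, 50
#' reliability repeats.
#'
#' @param enorm_thresh motion-derivative norm threshold, mm.
#' @param outlier_frac volume outlier-fraction threshold (inclusive).
#' @param poly_order drift polynomial order.
#' @param wm_radius local white-matter sphere radius, mm.
#' @param fwhm within-depth smoothing kernel FWHM, mm.
#' @param n_depths cortical depth count.
#' @param n_nodes columnar parcellation size for hubness.
#' @param k profile cluster count.
#' @param n_rep reliability repeats / null pairs.
#' @param sampling volume-to-surface mode, `"trilinear"` or
#'   `"upsample5_nearest"` (default; projects after a virtual 5x grid
#'   upsampling so no cross-tissue averaging enters the laminar samples).
#' @param compute_hubness also compute the global hubness map.
#' @param seed RNG seed for clustering/reliability.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(enorm_thresh = 0.4, outlier_frac = 0.10,
                            poly_order = 5, wm_radius = 15, fwhm = 3,
                            n_depths = 18, n_nodes = 1000, k = 2,
                            n_rep = 50, sampling = "upsample5_nearest",
                            compute_hubness = FALSE, seed = 1) {
  structure(list(enorm_thresh = enorm_thresh, outlier_frac = outlier_frac,
                 poly_order = poly_order, wm_radius = wm_radius,
                 fwhm = fwhm, n_depths = n_depths, n_nodes = n_nodes,
                 k = k, n_rep = n_rep, sampling = sampling,
                 compute_hubness = compute_hubness, seed = seed),
            class = "pipeline_params")
}

log_stage <- function(log, stage, detail) {
  message(sprintf("[%s] %s", stage, detail))
  rbind(log, tibble::tibble(stage = stage, detail = detail))
}

#' Run the full session-level pipeline
#'
#' Stage order: split the interleaved conditions (dummies dropped), compute
#' the dynamic-division contrast and its BOLD companion, compute volume
#' outlier fractions, censor pairs on motion and outliers, regress out
#' nuisance structure, optionally regress out an evoked response, sample
#' the residual volumes onto the equi-volume depth surfaces, smooth within
#' depth, and compute network connectivity-strength maps (and optionally
#' global hubness). Every stage logs its counts.
#'
#' @param session a `synthetic_session`, or a list with elements `series`
#'   (a `volume_series`), `motion` (a `motion_trace`), and `model` (a
#'   `cortical_model`-like list with `lmesh`, `masks`, `network_masks`,
#'   `affine`).
#' @param params a `pipeline_params`.
#' @param networks optional list of per-vertex logical network masks
#'   (default: the model's).
#' @param evoked optional regressor of no interest over kept pairs, with a
#'   `region` attribute (vertex mask) limiting its removal.
#' @return A list of class `session_result`: `paired`, `censor_mask`,
#'   `laminar` (smoothed `laminar_dataset` of residuals over kept pairs),
#'   `fcs` (list of `fcs_map`, one per network), `hubness` (optional),
#'   `log` (tibble).
#' @export
run_session <- function(session, params = pipeline_params(),
                        networks = NULL, evoked = NULL) {
  series <- session$series
  motion <- session$motion
  model <- session$model
  if (is.null(series) || is.null(motion) || is.null(model))
    stop("session must provide series, motion and model")
  log <- tibble::tibble(stage = character(), detail = character())

  log <- log_stage(log, "trim", sprintf("%d dummy volumes flagged",
                                        sum(series$dummy)))
  sp <- split_conditions(series)
  paired <- compute_vaper(sp$control, sp$nulled)
  log <- log_stage(log, "contrast",
                   sprintf("%d pairs, effective TR %.3f s",
                           dim(paired$vaper)[4], paired$effective_tr))

  brain <- model$masks$gm | model$masks$wm | model$masks$csf
  of <- outlier_fraction(series, mask = brain,
                         poly_order = params$poly_order)
  cm <- censor(motion, paired, enorm_thresh = params$enorm_thresh,
               outlier_frac = params$outlier_frac,
               outlier_fractions = of, dummy = series$dummy)
  log <- log_stage(log, "censor",
                   sprintf("%d of %d pairs censored",
                           sum(!cm$keep), length(cm$keep)))

  resid <- regress_nuisance(paired, motion, csf_mask = model$masks$csf,
                            wm_mask = model$masks$wm, censor_mask = cm,
                            mask = brain, poly_order = params$poly_order,
                            wm_radius = params$wm_radius)
  log <- log_stage(log, "nuisance",
                   sprintf("%d design columns, %d kept pairs",
                           ncol(resid$design), length(resid$kept_pairs)))

  lam <- sample_volume_to_surface(resid$data, model$lmesh,
                                  mode = params$sampling,
                                  affine = resid$affine)
  n_na <- sum(is.na(lam$values[, , 1]))
  log <- log_stage(log, "project",
                   sprintf("%d vertex-depth points missing", n_na))
  if (!is.null(evoked)) {
    region <- attr(evoked, "region")
    if (is.null(region)) region <- rep(TRUE, dim(lam$values)[1])
    lam <- regress_evoked(lam, as.numeric(evoked), region)
    log <- log_stage(log, "evoked", "evoked response regressed within region")
  }
  lam <- smooth_within_depth(lam, fwhm = params$fwhm)
  log <- log_stage(log, "smooth", sprintf("FWHM %.1f mm within depth",
                                          params$fwhm))

  if (is.null(networks)) {
    networks <- lapply(seq_len(ncol(model$network_masks)),
                       function(i) model$network_masks[, i])
    names(networks) <- vapply(model$config$networks, `[[`, character(1),
                              "name")
  }
  fcs <- lapply(networks, function(msk) network_fcs(lam, msk))
  log <- log_stage(log, "fcs", sprintf("%d network maps", length(fcs)))

  hub <- NULL
  if (isTRUE(params$compute_hubness)) {
    K <- min(params$n_nodes, dim(model$lmesh$coords)[1])
    nodes <- columnar_parcellation(model$lmesh, K = K, seed = params$seed)
    hub <- global_hubness(lam, nodes)
    log <- log_stage(log, "hubness", sprintf("K = %d nodes", K))
  }
  structure(list(paired = paired, censor_mask = cm, laminar = lam,
                 fcs = fcs, hubness = hub, log = log),
            class = "session_result")
}

## combine per-network fcs maps into one vertex x depth matrix
combine_fcs_maps <- function(fcs_list) {
  vals <- NULL
  for (m in fcs_list) {
    v <- m$values
    if (is.null(vals)) vals <- v
    else {
      fill <- !is.na(v)
      vals[fill] <- v[fill]
    }
  }
  vals
}

#' Run the group-level pipeline
#'
#' Runs each session, registers its connectivity maps depth-wise to the
#' template, averages them on the template, clusters the group-mean laminar
#' profiles within the network region, and quantifies reliability by
#' split-half Dice against the random-pattern null.
#'
#' @param group a `synthetic_group` (or list with `sessions`, `maps`,
#'   `template`).
#' @param params a `pipeline_params`.
#' @param region logical template-vertex mask to cluster (default: union
#'   of the template network masks).
#' @return A list of class `group_result`: `session_maps` (registered
#'   vertex x depth matrices), `group_map`, `parcellation`, `reliability`
#'   (a `laminar_reliability`, when >= 4 sessions), `log`.
#' @export
run_group <- function(group, params = pipeline_params(), region = NULL) {
  ns <- length(group$sessions)
  if (ns < 2) stop("need at least 2 sessions")
  template <- group$template
  if (is.null(region)) region <- rowSums(template$network_masks) > 0
  session_maps <- vector("list", ns)
  log <- tibble::tibble(stage = character(), detail = character())
  for (s in seq_len(ns)) {
    res <- run_session(group$sessions[[s]], params)
    vals <- combine_fcs_maps(res$fcs)
    M <- group$maps[[s]]$matrix
    session_maps[[s]] <- as.matrix(M %*% vals)
    log <- log_stage(log, "session", sprintf("session %d registered", s))
  }
  group_map <- Reduce(`+`, session_maps) / ns
  parc <- kmeans_profiles(group_map, region, k = params$k,
                          seed = params$seed)
  log <- log_stage(log, "cluster",
                   sprintf("k = %d over %d region vertices",
                           params$k, sum(region)))
  rel <- NULL
  if (ns >= 4) {
    rel <- assess_reliability(session_maps, region, n_rep = params$n_rep,
                              k = params$k, seed = params$seed)
    log <- log_stage(log, "reliability",
                     sprintf("split-half Dice %.3f vs null %.3f",
                             mean(rel$dice_values), mean(rel$null_dice)))
  }
  structure(list(session_maps = session_maps, group_map = group_map,
                 parcellation = parc, reliability = rel, region = region,
                 log = log),
            class = "group_result")
}

#' Voxel-count bookkeeping for an upsampled grid
#'
#' Product of the grid dimensions times the cubed per-axis upsampling
#' factor; used for memory planning and logged at pipeline startup.
#'
#' @param dims integer length 3.
#' @param upsample per-axis upsampling factor.
#' @return Voxel count (numeric, exact for counts below 2^53).
#' @export
grid_bookkeeping <- function(dims, upsample) {
  stopifnot(length(dims) == 3, all(dims > 0), upsample > 0,
            dims == as.integer(dims), upsample == as.integer(upsample))
  out <- prod(as.numeric(dims)) * as.numeric(upsample)^3
  if (out >= 2^53) stop("voxel count exceeds exact integer range")
  out
}

#' Vertex-count bookkeeping for laminar surface data
#' @param vertices vertex count of one depth surface.
#' @param depths number of cortical depths.
#' @return Total vertex count across depths.
#' @export
laminar_size <- function(vertices, depths) {
  stopifnot(vertices > 0, depths > 0)
  out <- as.numeric(vertices) * as.numeric(depths)
  if (out >= 2^53) stop("vertex count exceeds exact integer range")
  out
}

#' Read or write a pipeline configuration
#'
#' The configuration is stored as YAML and round-trips losslessly through
#' [pipeline_params()].
#'
#' @param path file path.
#' @param params a `pipeline_params`.
#' @return `read_pipeline_config()` returns a `pipeline_params`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_params, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
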