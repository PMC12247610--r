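#' Fisher z-transform of a correlation
#'
#' `atanh(r)` with `|r|` clipped to `1 - 1e-7` so that perfectly correlated
#' series map to a large finite value (about 8.406) instead of infinity.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1")
  clip <- 1 - 1e-7
  atanh(pmin(pmax(r, -clip), clip))
}

#' Laminar functional connectivity strength map
#'
#' Per-(vertex, depth) mean of the strictly positive Fisher-z-transformed
#' Pearson correlations with a defined target set; 0 when no correlation is
#' positive, `NA` where undefined (zero variance or too few time points).
#'
#' @param values numeric vertex x depth matrix.
#' @param network logical vertex mask the map is defined on (`NULL` for
#'   whole cortex).
#' @param n_timepoints number of time points used.
#' @return An object of class `fcs_map`.
#' @export
fcs_map <- function(values, network = NULL, n_timepoints = NA_integer_) {
  structure(list(values = values, network = network,
                 n_timepoints = n_timepoints),
            class = "fcs_map")
}

#' @export
print.fcs_map <- function(x, ...) {
  cat(sprintf("<fcs_map> %d vertices x %d depths (n = %s time points)\n",
              nrow(x$values), ncol(x$values), x$n_timepoints))
  invisible(x)
}

## time x series matrix from a laminar_dataset restricted to vertex indices;
## columns ordered vertex-major (all depths of vertex 1, then vertex 2, ...)
laminar_series_matrix <- function(data, vertices, kept = NULL) {
  vals <- data$values
  nt <- dim(vals)[3]
  if (is.null(kept)) kept <- seq_len(nt)
  D <- dim(vals)[2]
  m <- matrix(0, length(kept), length(vertices) * D)
  for (i in seq_along(vertices))
    m[, (i - 1) * D + seq_len(D)] <- t(vals[vertices[i], , kept])
  m
}

## mean strictly positive fisher z per row of a correlation matrix,
## honoring an exclusion mask (TRUE = excluded)
mean_positive_z <- function(R, exclude = NULL) {
  Z <- fisher_z(R)
  if (!is.null(exclude)) Z[exclude] <- NA
  pos <- !is.na(Z) & Z > 0
  any_t <- rowSums(!is.na(Z)) > 0
  s <- rowSums(Z * pos, na.rm = TRUE)
  n <- rowSums(pos)
  out <- ifelse(n > 0, s / pmax(n, 1L), 0)
  out[!any_t] <- NA_real_
  out
}

#' Network functional connectivity strength
#'
#' For every vertex and depth within a network, correlates its time course
#' with the network's other vertex-depth series, Fisher-z transforms the
#' correlations, and averages the strictly positive values (0 when none are
#' positive). All depths of the source vertex itself are excluded from its
#' target set; `targets = "same_depth"` further restricts targets to the
#' source depth.
#'
#' @param data a `laminar_dataset` of residual time series.
#' @param network logical per vertex, or integer vertex indices.
#' @param censor_keep optional logical per time point.
#' @param targets `"all_depths"` (default) or `"same_depth"`.
#' @param min_timepoints minimum kept time points (default 8).
#' @return An `fcs_map` with `NA` outside the network.
#' @export
network_fcs <- function(data, network, censor_keep = NULL,
                        targets = c("all_depths", "same_depth"),
                        min_timepoints = 8) {
  targets <- match.arg(targets)
  nv <- dim(data$values)[1]
  D <- dim(data$values)[2]
  verts <- if (is.logical(network)) which(network) else as.integer(network)
  if (length(verts) == 0) stop("network mask is empty")
  kept <- if (is.null(censor_keep)) seq_len(dim(data$values)[3]) else which(censor_keep)
  if (length(kept) < min_timepoints)
    stop(sprintf("fewer than %d kept time points", min_timepoints))
  M <- laminar_series_matrix(data, verts, kept)
  R <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  n <- ncol(M)
  excl <- matrix(FALSE, n, n)
  blocks <- rep(seq_along(verts), each = D)
  if (targets == "all_depths") {
    excl <- outer(blocks, blocks, `==`)
  } else {
    depth_of <- rep(seq_len(D), times = length(verts))
    excl <- outer(blocks, blocks, `==`) | outer(depth_of, depth_of, `!=`)
  }
  const <- apply(M, 2, function(x) stats::sd(x, na.rm = TRUE) == 0 ||
                   all(is.na(x)))
  fcs <- mean_positive_z(R, excl)
  fcs[const] <- NA_real_
  out <- matrix(NA_real_, nv, D)
  out[verts, ] <- matrix(fcs, ncol = D, byrow = TRUE)
  mask <- rep(FALSE, nv); mask[verts] <- TRUE
  fcs_map(out, mask, length(kept))
}

#' Seed-based laminar connectivity strength
#'
#' Correlates every target vertex-depth series with every seed series (all
#' depths of the seed vertices), Fisher-z transforms, and averages the
#' strictly positive values per target.
#'
#' @param data a `laminar_dataset`.
#' @param seed logical per vertex or vertex indices; the seed region.
#' @param targets logical per vertex or vertex indices; must be disjoint
#'   from the seed.
#' @param censor_keep optional logical per time point.
#' @param min_timepoints minimum kept time points (default 8).
#' @return An `fcs_map` defined over the target vertices.
#' @export
seed_fcs <- function(data, seed, targets, censor_keep = NULL,
                     min_timepoints = 8) {
  nv <- dim(data$values)[1]
  D <- dim(data$values)[2]
  sv <- if (is.logical(seed)) which(seed) else as.integer(seed)
  tv <- if (is.logical(targets)) which(targets) else as.integer(targets)
  if (length(sv) == 0) stop("empty seed")
  if (length(intersect(sv, tv)) > 0) stop("seed and targets must be disjoint")
  kept <- if (is.null(censor_keep)) seq_len(dim(data$values)[3]) else which(censor_keep)
  if (length(kept) < min_timepoints)
    stop(sprintf("fewer than %d kept time points", min_timepoints))
  S <- laminar_series_matrix(data, sv, kept)
  Tm <- laminar_series_matrix(data, tv, kept)
  R <- suppressWarnings(stats::cor(Tm, S, use = "pairwise.complete.obs"))
  fcs <- mean_positive_z(R)
  out <- matrix(NA_real_, nv, D)
  out[tv, ] <- matrix(fcs, ncol = D, byrow = TRUE)
  mask <- rep(FALSE, nv); mask[tv] <- TRUE
  fcs_map(out, mask, length(kept))
}

#' Columnar parcellation of the cortical sheet
#'
#' Partitions the vertices into `K` spatially compact, contiguous nodes by
#' k-means on mid-depth vertex coordinates followed by contiguity repair
#' (disconnected fragments of a node are reassigned to the majority label
#' of their neighbors). Every node spans all cortical depths (a column).
#'
#' @param lmesh a `laminar_mesh`.
#' @param K number of nodes (default 1000).
#' @param seed RNG seed for reproducibility.
#' @return An object of class `node_parcellation`: integer `labels` per
#'   vertex and node count `K`.
#' @export
columnar_parcellation <- function(lmesh, K = 1000, seed = 1) {
  nv <- dim(lmesh$coords)[1]
  if (K > nv) stop("K exceeds vertex count")
  mid <- lmesh$coords[, max(1L, round(lmesh$n_depths / 2)), ]
  if (K == nv) {
    labels <- seq_len(nv)
  } else {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    km <- stats::kmeans(mid, centers = K, nstart = 5, iter.max = 100)
    labels <- km$cluster
    labels <- repair_contiguity(labels, lmesh$base)
  }
  structure(list(labels = labels, K = K), class = "node_parcellation")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

## reassign disconnected fragments of each label to neighbor majority
repair_contiguity <- function(labels, mesh, max_pass = 10) {
  A <- vertex_adjacency(mesh)
  nb <- apply_adj_list(A)
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    for (lab in unique(labels)) {
      members <- which(labels == lab)
      if (length(members) <= 1) next
      comp <- connected_components(members, nb)
      if (length(comp) == 1) next
      sizes <- lengths(comp)
      keep_main <- which.max(sizes)
      for (ci in seq_along(comp)) {
        if (ci == keep_main) next
        for (v in comp[[ci]]) {
          nl <- labels[nb[[v]]]
          nl <- nl[nl != lab]
          if (length(nl) > 0) {
            labels[v] <- as.integer(names(which.max(table(nl))))
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  labels
}

apply_adj_list <- function(A) {
  n <- nrow(A)
  Ai <- Matrix::summary(A)
  split(Ai$j, factor(Ai$i, levels = seq_len(n)))
}

connected_components <- function(members, nb) {
  in_set <- logical(length(nb)); in_set[members] <- TRUE
  seen <- logical(length(nb))
  comps <- list()
  for (v in members) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, u)
      nbu <- nb[[u]]
      nxt <- nbu[in_set[nbu] & !seen[nbu]]
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    comps[[length(comps) + 1]] <- comp
  }
  comps
}

#' Global hubness map
#'
#' The connectivity strength of every vertex at every depth with the whole
#' cortex, computed against representative time series of a columnar
#' parcellation: each node series is the mean over all its vertex-depth
#' series, and hubness is the mean strictly positive Fisher z of the
#' correlations with all `K` nodes (the vertex's own node included by
#' default).
#'
#' @param data a `laminar_dataset`.
#' @param nodes a `node_parcellation`.
#' @param censor_keep optional logical per time point.
#' @param exclude_own exclude the vertex's own node (default `FALSE`).
#' @return An `fcs_map` over the whole mesh.
#' @export
global_hubness <- function(data, nodes, censor_keep = NULL,
                           exclude_own = FALSE) {
  nv <- dim(data$values)[1]
  D <- dim(data$values)[2]
  kept <- if (is.null(censor_keep)) seq_len(dim(data$values)[3]) else which(censor_keep)
  K <- nodes$K
  if (any(tabulate(nodes$labels, K) == 0)) stop("empty node in parcellation")
  node_series <- matrix(0, length(kept), K)
  for (k in seq_len(K)) {
    vs <- which(nodes$labels == k)
    m <- laminar_series_matrix(data, vs, kept)
    node_series[, k] <- rowMeans(m, na.rm = TRUE)
  }
  M <- laminar_series_matrix(data, seq_len(nv), kept)
  R <- suppressWarnings(stats::cor(M, node_series,
                                   use = "pairwise.complete.obs"))
  excl <- NULL
  if (exclude_own) {
    own <- rep(nodes$labels, each = D)
    excl <- matrix(FALSE, nrow(R), K)
    excl[cbind(seq_len(nrow(R)), own)] <- TRUE
  }
  fcs <- mean_positive_z(R, excl)
  fcs_map(matrix(fcs, nv, D, byrow = TRUE), NULL, length(kept))
}

#' Laminar profile of a connectivity map within an ROI
#'
#' Averages an FCS map over the ROI vertices at each depth, per session;
#' optionally rescales each session's profile to the 0-1 range (shape
#' normalization, for presentation only — clustering always uses raw
#' profiles); then returns the across-session mean and SEM per depth.
#'
#' @param maps an `fcs_map`, a vertex x depth matrix, or a list of them
#'   (one per session).
#' @param roi logical per vertex or vertex indices.
#' @param normalize rescale each session profile to `[0, 1]` (default
#'   `FALSE`). A constant profile is set to 0.5 with a warning.
#' @return A tibble with columns `depth`, `mean`, `sem`, `n`.
#' @export
extract_profile <- function(maps, roi, normalize = FALSE) {
  if (inherits(maps, "fcs_map") || is.matrix(maps)) maps <- list(maps)
  idx <- if (is.logical(roi)) which(roi) else as.integer(roi)
  if (length(idx) == 0) stop("roi is empty")
  profs <- vapply(maps, function(m) {
    v <- if (inherits(m, "fcs_map")) m$values else m
    colMeans(v[idx, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(if (inherits(maps[[1]], "fcs_map")) maps[[1]]$values else maps[[1]])))
  profs <- matrix(profs, ncol = length(maps))   # depth x session
  if (normalize) {
    profs <- apply(profs, 2, function(p) {
      rng <- range(p)
      if (diff(rng) == 0) {
        warning("constant profile; normalized values set to 0.5")
        rep(0.5, length(p))
      } else (p - rng[1]) / diff(rng)
    })
  }
  ns <- ncol(profs)
  mu <- rowMeans(profs)
  sem <- if (ns > 1) apply(profs, 1, stats::sd) / sqrt(ns) else rep(0, nrow(profs))
  tibble::tibble(depth = seq_len(nrow(profs)), mean = mu, sem = sem, n = ns)
}
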