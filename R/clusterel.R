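#' k-means clustering of laminar connectivity profiles
#'
#' Groups vertices of a region by the shape of their connectivity-strength
#' profile across cortical depths, using `1 - Pearson r` between depth
#' profiles as the distance (profiles are standardized per Lloyd update, so
#' only shape matters, not scale). The best of `n_restarts` greedy
#' farthest-profile seedings by within-cluster distance sum is kept.
#'
#' For `k = 2` the cluster labels are anchored to their laminar semantics:
#' the cluster whose mean raw profile peaks in the middle band of depths
#' (the central third, depths 7-12 of 18) receives label 1
#' (feedforward-like, middle-peak); the other receives label 2
#' (feedback-like, superficial-peak). If both peak inside (or both outside)
#' the band, the cluster with the smaller peak-depth index becomes label 1.
#' Vertices with missing or zero-variance profiles get label 0
#' (unclassified) and are excluded from the fit.
#'
#' @param map an `fcs_map` or a vertex x depth matrix.
#' @param region logical per vertex or vertex indices; defaults to the
#'   map's own network mask.
#' @param k number of clusters (default 2; the reliability tooling assumes
#'   2).
#' @param n_restarts number of seedings (default 10).
#' @param seed RNG seed.
#' @return An object of class `laminar_parcellation`: integer `labels` per
#'   vertex (0 = unclassified, `NA` outside the region), `centers` (k x
#'   depth matrix of mean raw profiles, rows in label order), `region`
#'   mask, `k`.
#' @export
kmeans_profiles <- function(map, region = NULL, k = 2, n_restarts = 10,
                            seed = 1) {
  vals <- if (inherits(map, "fcs_map")) map$values else map
  nv <- nrow(vals)
  D <- ncol(vals)
  if (is.null(region)) {
    region <- if (inherits(map, "fcs_map") && !is.null(map$network))
      map$network else rep(TRUE, nv)
  }
  idx <- if (is.logical(region)) which(region) else as.integer(region)
  P <- vals[idx, , drop = FALSE]
  usable <- apply(P, 1, function(p) all(is.finite(p)) && stats::sd(p) > 0)
  if (sum(usable) < k) stop("fewer than k usable profiles in region")
  U <- P[usable, , drop = FALSE]
  Us <- t(apply(U, 1, function(p) {
    p <- p - mean(p)
    p / sqrt(sum(p^2))
  }))
  n_distinct <- nrow(unique(round(Us, 10)))
  if (n_distinct < k)
    stop("fewer than k distinct profiles (correlation distance degenerate)")

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd_correlation(Us, k)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  cl <- best$cluster

  # anchored labeling from mean raw profiles
  centers_raw <- t(vapply(seq_len(k), function(g)
    colMeans(U[cl == g, , drop = FALSE]), numeric(D)))
  peaks <- apply(centers_raw, 1, which.max)
  band <- c(floor(D / 3) + 1, ceiling(2 * D / 3))
  if (k == 2) {
    in_band <- peaks >= band[1] & peaks <= band[2]
    first <- if (sum(in_band) == 1) which(in_band) else which.min(peaks)
    order_k <- c(first, setdiff(1:2, first))
  } else {
    order_k <- order(peaks)
  }
  relabel <- integer(k); relabel[order_k] <- seq_len(k)
  cl <- relabel[cl]
  centers <- centers_raw[order_k, , drop = FALSE]

  labels <- rep(NA_integer_, nv)
  labels[idx] <- 0L
  labels[idx[usable]] <- cl
  mask <- rep(FALSE, nv); mask[idx] <- TRUE
  structure(list(labels = labels, centers = centers, region = mask, k = k),
            class = "laminar_parcellation")
}

#' @export
print.laminar_parcellation <- function(x, ...) {
  tb <- table(factor(x$labels[x$region], levels = 0:x$k))
  cat(sprintf("<laminar_parcellation> k = %d over %d region vertices (%s)\n",
              x$k, sum(x$region),
              paste(sprintf("label %s: %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

## Lloyd iterations with correlation (cosine on standardized rows) distance;
## greedy farthest-profile seeding from a random start
lloyd_correlation <- function(Us, k, max_iter = 100) {
  n <- nrow(Us)
  centers <- matrix(0, k, ncol(Us))
  first <- sample.int(n, 1)
  chosen <- first
  for (g in 2:k) {
    sim <- Us %*% t(Us[chosen, , drop = FALSE])
    dmin <- apply(1 - sim, 1, min)
    dmin[chosen] <- -Inf
    chosen <- c(chosen, which.max(dmin))
  }
  centers <- Us[chosen, , drop = FALSE]
  cl <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    sim <- Us %*% t(centers)
    new_cl <- max.col(sim, ties.method = "first")
    for (g in seq_len(k)) {
      if (!any(new_cl == g)) {               # re-seed empty cluster
        d_own <- 1 - sim[cbind(seq_len(n), new_cl)]
        far <- which.max(d_own)
        new_cl[far] <- g
      }
    }
    if (it > 1 && all(new_cl == cl)) break
    cl <- new_cl
    for (g in seq_len(k)) {
      m <- colMeans(Us[cl == g, , drop = FALSE])
      m <- m - mean(m)
      nm <- sqrt(sum(m^2))
      centers[g, ] <- if (nm > 0) m / nm else Us[sample.int(n, 1), ]
    }
  }
  objective <- sum(1 - (Us %*% t(centers))[cbind(seq_len(n), cl)])
  list(cluster = cl, centers = centers, objective = objective)
}

#' Dice similarity between two-cluster parcellations
#'
#' Computes, for each anchored label (1 and 2), the Dice coefficient
#' `2|A_l  B_l| / (|A_l| + |B_l|)` and returns the unweighted mean.
#' Labels are matched by their anchored semantics (no permutation search).
#' Unclassified (0 or `NA`) vertices are excluded pairwise; a label empty
#' in both parcellations is skipped.
#'
#' @param A,B `laminar_parcellation` objects or integer label vectors on
#'   the same region.
#' @param labels label values to compare (default `c(1, 2)`).
#' @return Mean Dice coefficient in `[0, 1]`.
#' @export
dice_parcellation <- function(A, B, labels = c(1L, 2L)) {
  a <- if (inherits(A, "laminar_parcellation")) A$labels else A
  b <- if (inherits(B, "laminar_parcellation")) B$labels else B
  if (length(a) != length(b)) stop("parcellations must share a region")
  ok <- !is.na(a) & !is.na(b) & a != 0L & b != 0L
  a <- a[ok]; b <- b[ok]
  ds <- numeric(0)
  for (l in labels) {
    na <- sum(a == l); nb <- sum(b == l)
    if (na + nb == 0) next
    ds <- c(ds, 2 * sum(a == l & b == l) / (na + nb))
  }
  if (length(ds) == 0) stop("all labels empty in both parcellations")
  mean(ds)
}

#' Dice similarity between two binary masks
#' @param A,B logical vectors on the same vertex space.
#' @return `2|A  B| / (|A| + |B|)`.
#' @export
dice_binary <- function(A, B) {
  stopifnot(length(A) == length(B))
  A <- as.logical(A); B <- as.logical(B)
  denom <- sum(A) + sum(B)
  if (denom == 0) stop("both masks empty")
  2 * sum(A & B) / denom
}

#' Select the candidate component best matching an atlas network
#'
#' Thresholds each candidate z-map at `z > z_thresh` and returns the binary
#' map with the highest Dice similarity to the atlas mask (ties broken by
#' lower candidate index). Used to pick the ICA component representing a
#' functional network.
#'
#' @param candidates list of numeric per-vertex z-maps.
#' @param atlas_mask logical per vertex.
#' @param z_thresh z threshold (default 2, strict).
#' @return A list: `mask` (logical), `index`, `dice`.
#' @export
select_network_component <- function(candidates, atlas_mask, z_thresh = 2) {
  if (length(candidates) == 0) stop("no candidates")
  masks <- lapply(candidates, function(z) z > z_thresh)
  nonempty <- vapply(masks, any, logical(1))
  if (!any(nonempty)) stop("all thresholded candidate maps are empty")
  dice <- vapply(seq_along(masks), function(i) {
    if (!nonempty[i]) return(-Inf)
    dice_binary(masks[[i]], atlas_mask)
  }, numeric(1))
  if (max(dice) == 0)
    warning("no candidate overlaps the atlas; returning the first")
  best <- which.max(dice)
  list(mask = masks[[best]], index = best, dice = dice[best])
}

#' Group-level network mask from individual masks
#'
#' Vertex-wise mean of the binary masks (all on the template surface),
#' binarized at `mean >= threshold`.
#'
#' @param individual_masks list of logical vectors on the template.
#' @param threshold inclusion fraction (default 0.5, inclusive).
#' @return Logical mask.
#' @export
group_network_mask <- function(individual_masks, threshold = 0.5) {
  m <- Reduce(`+`, lapply(individual_masks, as.numeric)) /
    length(individual_masks)
  m >= threshold
}

#' Split-half reliability of laminar-profile parcellation
#'
#' Repeatedly splits the sessions into two random halves of (near-)equal
#' size, averages each half's connectivity map, clusters each mean map with
#' [kmeans_profiles()], and records the Dice similarity between the two
#' parcellations.
#'
#' @param session_maps list (length >= 4) of `fcs_map` or vertex x depth
#'   matrices on the template.
#' @param region logical per vertex or vertex indices.
#' @param n_rep number of random splits (default 50).
#' @param k clusters (default 2).
#' @param seed RNG seed.
#' @return Numeric vector of `n_rep` Dice coefficients.
#' @export
split_half_reliability <- function(session_maps, region, n_rep = 50, k = 2,
                                   seed = 1) {
  ns <- length(session_maps)
  if (ns < 4) stop("need at least 4 sessions for split-half reliability")
  mats <- lapply(session_maps, function(m)
    if (inherits(m, "fcs_map")) m$values else m)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  vapply(seq_len(n_rep), function(r) {
    half <- sample(ns, floor(ns / 2))
    m1 <- Reduce(`+`, mats[half]) / length(half)
    m2 <- Reduce(`+`, mats[-half]) / (ns - length(half))
    p1 <- kmeans_profiles(m1, region, k = k, seed = seed + 101 * r)
    p2 <- kmeans_profiles(m2, region, k = k, seed = seed + 101 * r + 1)
    dice_parcellation(p1, p2)
  }, numeric(1))
}

#' Dice null distribution from random two-label patterns
#'
#' Generates pairs of random parcellations by labeling every region vertex
#' 1 or 2 independently with probability 0.5 and computes the anchored
#' mean Dice per pair. Under this fair-label model the expected Dice is
#' 0.5.
#'
#' @param region logical mask, vertex indices, or a single integer vertex
#'   count.
#' @param n_pairs number of random pattern pairs (default 50).
#' @param seed RNG seed.
#' @return Numeric vector of `n_pairs` Dice coefficients.
#' @export
random_pattern_null <- function(region, n_pairs = 50, seed = 1) {
  n <- if (length(region) == 1 && is.numeric(region)) as.integer(region)
  else if (is.logical(region)) sum(region) else length(region)
  if (n < 1) stop("region is empty")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  vapply(seq_len(n_pairs), function(p) {
    a <- sample(c(1L, 2L), n, replace = TRUE)
    b <- sample(c(1L, 2L), n, replace = TRUE)
    dice_parcellation(a, b)
  }, numeric(1))
}

#' Compare observed Dice values with a null distribution
#'
#' Two-sample t-test (pooled variance by default, Welch optional) between
#' observed and null Dice coefficients.
#'
#' @param observed,null numeric vectors (length >= 2 each).
#' @param var_equal pooled-variance t-test (default `TRUE`).
#' @return A list with `t_stat`, `p_value`, `df`, `mean_observed`,
#'   `mean_null`.
#' @export
compare_dice <- function(observed, null, var_equal = TRUE) {
  stopifnot(length(observed) >= 2, length(null) >= 2)
  s1 <- stats::sd(observed); s2 <- stats::sd(null)
  if (s1 == 0 && s2 == 0) {
    if (mean(observed) == mean(null))
      return(list(t_stat = 0, p_value = 1,
                  df = length(observed) + length(null) - 2,
                  mean_observed = mean(observed), mean_null = mean(null)))
    return(list(t_stat = sign(mean(observed) - mean(null)) * Inf,
                p_value = 0, df = length(observed) + length(null) - 2,
                mean_observed = mean(observed), mean_null = mean(null)))
  }
  tt <- stats::t.test(observed, null, var.equal = var_equal)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_observed = mean(observed), mean_null = mean(null))
}

#' Reliability assessment of a laminar parcellation
#'
#' Convenience wrapper combining [split_half_reliability()],
#' [random_pattern_null()], and [compare_dice()].
#'
#' @inheritParams split_half_reliability
#' @param n_rep number of split-half repeats and null pairs (default 50).
#' @return An object of class `laminar_reliability` with fields
#'   `dice_values`, `null_dice`, `t_stat`, `p_value`, `n_pairs`.
#' @export
assess_reliability <- function(session_maps, region, n_rep = 50, k = 2,
                               seed = 1) {
  obs <- split_half_reliability(session_maps, region, n_rep = n_rep, k = k,
                                seed = seed)
  nul <- random_pattern_null(region, n_pairs = n_rep, seed = seed + 1)
  cmp <- compare_dice(obs, nul)
  structure(list(dice_values = obs, null_dice = nul,
                 t_stat = cmp$t_stat, p_value = cmp$p_value,
                 n_pairs = n_rep), class = "laminar_reliability")
}

#' @export
print.laminar_reliability <- function(x, ...) {
  cat(sprintf(paste0("<laminar_reliability> split-half Dice %.3f +/- %.3f vs ",
                     "null %.3f +/- %.3f (t = %.2f, p = %.3g, %d pairs)\n"),
              mean(x$dice_values), stats::sd(x$dice_values),
              mean(x$null_dice), stats::sd(x$null_dice),
              x$t_stat, x$p_value, x$n_pairs))
  invisible(x)
}
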