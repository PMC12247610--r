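#' Head-motion trace
#'
#' Six rigid-body parameters per volume (3 translations in mm, 3 rotations
#' in degrees) plus their backward differences. Rotation differences are
#' used numerically as mm-equivalents in the Euclidean norm, the common
#' convention for the 0.4 mm censoring threshold; an optional head radius
#' converts rotations to arc length instead.
#'
#' @param params numeric matrix, volumes x 6.
#' @param head_radius_mm optional radius for converting rotation degrees to
#'   mm of arc before differencing; `NULL` (default) uses degrees as mm.
#' @return An object of class `motion_trace` with fields `params` and
#'   `derivative` (first row zero by convention).
#' @export
motion_trace <- function(params, head_radius_mm = NULL) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6)
  p <- params
  if (!is.null(head_radius_mm))
    p[, 4:6] <- p[, 4:6] * pi / 180 * head_radius_mm
  d <- rbind(rep(0, 6), diff(p))
  structure(list(params = params, derivative = d), class = "motion_trace")
}

#' Euclidean norm of motion derivatives
#' @param motion a `motion_trace`.
#' @return Numeric vector, one value per volume.
#' @export
motion_enorm <- function(motion) {
  sqrt(rowSums(motion$derivative^2))
}

#' Volume-wise outlier fraction relative to a polynomial trend
#'
#' Fits a per-voxel polynomial trend (orthogonal basis of the given order,
#' plus intercept) across time and flags a voxel at a time point when its
#' absolute residual exceeds `c_mad` times the voxel's median absolute
#' deviation of residuals. The fraction of flagged in-mask voxels is
#' returned per volume. Zero-variance voxels are never flagged.
#'
#' @param data 4D array or a `volume_series`.
#' @param mask logical 3D array restricting the computation (default: all
#'   voxels with nonzero temporal variance).
#' @param poly_order polynomial trend order (default 5).
#' @param c_mad residual threshold in MADs (default 4.5).
#' @return Numeric vector of per-volume outlier fractions.
#' @export
outlier_fraction <- function(data, mask = NULL, poly_order = 5, c_mad = 4.5) {
  if (inherits(data, "volume_series")) data <- data$data
  if (length(dim(data)) == 4) {
    dm <- dim(data)
    Y <- matrix(data, prod(dm[1:3]), dm[4])
  } else {
    Y <- as.matrix(data)
  }
  if (!is.null(mask)) Y <- Y[as.vector(mask), , drop = FALSE]
  nt <- ncol(Y)
  if (nt < poly_order + 2) stop("need at least poly_order + 2 time points")
  ok <- apply(Y, 1, function(r) all(is.finite(r))) &
    (matrixStats_rowVars(Y) > 0)
  Yk <- t(Y[ok, , drop = FALSE])                 # time x voxel
  X <- cbind(1, stats::poly(seq_len(nt), degree = poly_order))
  Q <- qr.Q(qr(X))
  R <- Yk - Q %*% crossprod(Q, Yk)
  madv <- apply(R, 2, function(r) stats::mad(r, constant = 1))
  # a MAD at numerical-noise level (relative to the signal scale) means the
  # trend absorbed the series exactly; such voxels are never flagged
  floor_v <- 1e-10 * apply(abs(Yk), 2, max)
  flag <- abs(R) > rep(c_mad * madv, each = nt)
  flag[, madv <= floor_v] <- FALSE
  rowSums(flag) / max(1L, sum(ok))
}

## row variances without matrixStats (not installed); na.rm not needed here
matrixStats_rowVars <- function(Y) {
  m <- rowMeans(Y)
  rowSums((Y - m)^2) / (ncol(Y) - 1)
}

#' Censor mask over contrast pairs
#'
#' A pair of interleaved volumes is censored when the Euclidean norm of the
#' motion-parameter derivatives of either constituent volume exceeds
#' `enorm_thresh`, or when the outlier fraction of either volume is at
#' least `outlier_frac` (inclusive), or when either volume is a dummy.
#'
#' @param motion a `motion_trace` aligned to the original volume series.
#' @param paired a `paired_series` (provides the pair-to-volume mapping).
#' @param enorm_thresh motion derivative norm threshold in mm (default 0.4).
#' @param outlier_frac outlier-fraction threshold (default 0.10, inclusive).
#' @param outlier_fractions per-volume outlier fractions aligned to the
#'   original series (e.g. from [outlier_fraction()]); `NULL` skips the
#'   outlier criterion.
#' @param dummy logical per original volume.
#' @return An object of class `censor_mask`: logical `keep` per pair plus a
#'   list of reasons (subsets of `"dummy"`, `"motion"`, `"outlier"`).
#' @export
censor <- function(motion, paired, enorm_thresh = 0.4, outlier_frac = 0.10,
                   outlier_fractions = NULL, dummy = NULL) {
  pv <- paired$pair_volumes
  en <- motion_enorm(motion)
  np <- nrow(pv)
  reasons <- vector("list", np)
  keep <- rep(TRUE, np)
  for (p in seq_len(np)) {
    vols <- pv[p, ]
    r <- character(0)
    if (!is.null(dummy) && any(dummy[vols])) r <- c(r, "dummy")
    if (any(en[vols] > enorm_thresh)) r <- c(r, "motion")
    if (!is.null(outlier_fractions) &&
        any(outlier_fractions[vols] >= outlier_frac)) r <- c(r, "outlier")
    reasons[[p]] <- r
    keep[p] <- length(r) == 0
  }
  if (!any(keep)) stop("no usable data: all pairs censored")
  structure(list(keep = keep, reasons = reasons), class = "censor_mask")
}

#' @export
print.censor_mask <- function(x, ...) {
  cat(sprintf("<censor_mask> %d of %d pairs kept\n", sum(x$keep),
              length(x$keep)))
  invisible(x)
}

## spherical-kernel convolution over a 3D grid via FFT (zero padded)
sphere_convolve <- function(arr, radius_mm, voxel_size) {
  dm <- dim(arr)
  rv <- ceiling(radius_mm / voxel_size)
  pd <- dm + 2 * rv
  kern <- array(0, pd)
  off <- expand.grid(x = -rv[1]:rv[1], y = -rv[2]:rv[2], z = -rv[3]:rv[3])
  d2 <- (off$x * voxel_size[1])^2 + (off$y * voxel_size[2])^2 +
    (off$z * voxel_size[3])^2
  inside <- d2 <= radius_mm^2
  ix <- cbind((off$x[inside]) %% pd[1] + 1,
              (off$y[inside]) %% pd[2] + 1,
              (off$z[inside]) %% pd[3] + 1)
  kern[ix] <- 1
  pad <- array(0, pd)
  pad[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- arr
  out <- Re(stats::fft(stats::fft(pad) * stats::fft(kern), inverse = TRUE)) /
    prod(pd)
  out[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])]
}

#' Voxel-wise local white-matter regressor
#'
#' For every voxel, the mean raw signal of white-matter voxels within a
#' sphere of `radius_mm` (local white-matter nuisance regressor). Voxels
#' with no white matter in range fall back to the global white-matter mean.
#'
#' @param data 4D array (x, y, z, time).
#' @param wm_mask logical 3D array.
#' @param radius_mm sphere radius (default 15 mm).
#' @param voxel_size numeric length 3, mm.
#' @return 4D array of local white-matter time series.
#' @export
local_wm_regressor <- function(data, wm_mask, radius_mm = 15,
                               voxel_size = c(1, 1, 1)) {
  dm <- dim(data)
  wm <- array(as.numeric(wm_mask), dm[1:3])
  den <- sphere_convolve(wm, radius_mm, voxel_size)
  out <- array(0, dm)
  wm_flat <- as.vector(wm_mask)
  for (t in seq_len(dm[4])) {
    vol <- data[, , , t]
    vol[!is.finite(vol)] <- 0
    num <- sphere_convolve(vol * wm, radius_mm, voxel_size)
    loc <- num / pmax(den, .Machine$double.eps)
    wm_mean <- mean(vol[wm_flat])
    loc[den < 0.5] <- wm_mean
    out[, , , t] <- loc
  }
  out
}

## orthogonal polynomial + motion + derivative + CSF design over kept pairs
nuisance_design <- function(motion_pairs, csf_series, poly_order, n_kept) {
  polys <- cbind(1, stats::poly(seq_len(n_kept), degree = poly_order))
  d <- rbind(rep(0, 6), diff(motion_pairs))
  X <- cbind(polys, motion_pairs, d, csf = csf_series)
  colnames(X) <- c(paste0("poly", 0:poly_order),
                   paste0("mot", 1:6), paste0("dmot", 1:6), "csf")
  X
}

#' Nuisance regression of paired contrast series
#'
#' Regresses, voxel by voxel over the kept (non-censored) pairs, the
#' contrast series against motion parameters and their derivatives,
#' orthogonal polynomial drift terms up to `poly_order`, the mean
#' ventricular CSF signal, and a voxel-wise local white-matter regressor
#' (mean white-matter signal within `wm_radius`). Residuals are divided by
#' each voxel's pre-regression temporal mean, yielding unit-free
#' fluctuation series. Collinear design columns are dropped with a
#' warning; voxels with nonpositive mean are set missing.
#'
#' @param paired a `paired_series`.
#' @param motion a `motion_trace` on the original volume grid; pair-level
#'   regressors average the pair's two volumes.
#' @param csf_mask,wm_mask logical 3D arrays.
#' @param censor_mask a `censor_mask`; `NULL` keeps all pairs.
#' @param mask logical 3D analysis mask (default: gray matter = everywhere
#'   finite).
#' @param poly_order drift polynomial order (default 5).
#' @param wm_radius local white-matter sphere radius in mm (default 15).
#' @param series which component to residualize, `"vaper"` or `"bold"`.
#' @return A list: `data` (4D residual array over kept pairs), `kept_pairs`
#'   (indices into the original pairs), `design` (the shared design
#'   matrix), `paired` metadata carried over.
#' @export
regress_nuisance <- function(paired, motion, csf_mask, wm_mask,
                             censor_mask = NULL, mask = NULL,
                             poly_order = 5, wm_radius = 15,
                             series = c("vaper", "bold")) {
  series <- match.arg(series)
  Yarr <- paired[[series]]
  dm <- dim(Yarr)
  keep <- if (is.null(censor_mask)) rep(TRUE, dm[4]) else censor_mask$keep
  kept <- which(keep)
  nk <- length(kept)
  if (nk < poly_order + 15)
    stop("too few kept pairs for the nuisance design")
  pv <- paired$pair_volumes[kept, , drop = FALSE]
  mot_pairs <- (motion$params[pv[, 1], , drop = FALSE] +
                  motion$params[pv[, 2], , drop = FALSE]) / 2
  csf <- vapply(kept, function(p) {
    v <- Yarr[, , , p]
    mean(v[csf_mask], na.rm = TRUE)
  }, numeric(1))
  X <- nuisance_design(mot_pairs, csf, poly_order, nk)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropc <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("dropping collinear design columns: ",
            paste(dropc, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  Q <- qr.Q(qx)

  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  vox <- which(as.vector(mask))
  nxyz <- prod(dm[1:3])
  Y <- matrix(Yarr, nxyz, dm[4])[vox, kept, drop = FALSE]
  mu <- rowMeans(Y, na.rm = TRUE)
  bad_mu <- !is.finite(mu) | mu <= 0 | apply(Y, 1, function(r) any(!is.finite(r)))

  Wk <- local_wm_regressor(Yarr[, , , kept, drop = FALSE], wm_mask,
                           radius_mm = wm_radius,
                           voxel_size = paired$voxel_size)
  W <- matrix(Wk, nxyz, nk)[vox, , drop = FALSE]

  Yt <- t(Y); Wt <- t(W)                        # time x voxel
  Ry <- Yt - Q %*% crossprod(Q, Yt)
  Rw <- Wt - Q %*% crossprod(Q, Wt)
  ww <- colSums(Rw^2)
  beta <- ifelse(ww > 1e-12, colSums(Ry * Rw) / pmax(ww, 1e-12), 0)
  Res <- Ry - sweep(Rw, 2, beta, `*`)
  Res <- sweep(Res, 2, mu, `/`)
  Res[, bad_mu] <- NA_real_

  out <- array(NA_real_, c(nxyz, nk))
  out[vox, ] <- t(Res)
  list(data = array(out, c(dm[1:3], nk)), kept_pairs = kept, design = X,
       affine = paired$affine, voxel_size = paired$voxel_size,
       effective_tr = paired$effective_tr)
}

#' Regress out an evoked response within a region
#'
#' Residualizes each vertex-depth time series inside `region_mask` against
#' a constant plus the given evoked regressor (a regressor of no interest,
#' e.g. the mean visual response during movie watching); series outside the
#' mask are returned unchanged. A zero-variance regressor is a no-op with a
#' warning.
#'
#' @param data a `laminar_dataset`.
#' @param evoked numeric regressor aligned to the data's time points.
#' @param region_mask logical per vertex.
#' @return A `laminar_dataset` of residuals.
#' @export
regress_evoked <- function(data, evoked, region_mask) {
  vals <- data$values
  nt <- dim(vals)[3]
  stopifnot(length(evoked) == nt)
  if (stats::sd(evoked) == 0) {
    warning("evoked regressor has zero variance; no regression applied")
    return(data)
  }
  idx <- which(region_mask)
  if (length(idx) == 0) return(data)
  X <- cbind(1, evoked)
  Q <- qr.Q(qr(X))
  for (d in seq_len(dim(vals)[2])) {
    Yt <- t(matrix(vals[idx, d, ], ncol = nt))   # time x vertex
    vals[idx, d, ] <- t(Yt - Q %*% crossprod(Q, Yt))
  }
  laminar_dataset(vals, data$mesh, data$session)
}
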