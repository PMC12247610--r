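#' Interleaved two-condition volume series
#'
#' Container for a 4D acquisition alternating between blood-nulled
#' (DANTE-prepared) and control conditions, or between MT-prepared and
#' control conditions for the anatomical run.
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param voxel_size numeric length 3, mm.
#' @param volume_tr volume repetition time in seconds.
#' @param schedule character vector, one of `"nulled"`, `"control"`,
#'   `"mt"`, `"mt_control"` per volume.
#' @param dummy logical per volume; dummy volumes are excluded from all
#'   analysis.
#' @param te echo time in seconds (metadata only).
#' @param affine 4 x 4 matrix mapping 1-based voxel indices to mm; defaults
#'   to a grid centered at the origin.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_size, volume_tr, schedule,
                          dummy = rep(FALSE, dim(data)[4]),
                          te = 0.020, affine = NULL) {
  stopifnot(length(dim(data)) == 4, volume_tr > 0)
  voxel_size <- rep_len(voxel_size, 3)
  if (length(schedule) != dim(data)[4])
    stop("schedule length must equal the number of volumes")
  if (is.null(affine)) affine <- centered_affine(dim(data)[1:3], voxel_size)
  structure(list(data = data, voxel_size = voxel_size,
                 volume_tr = volume_tr, te = te,
                 schedule = schedule, dummy = dummy, affine = affine,
                 volume_index = seq_along(schedule)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %dx%dx%d voxels x %d volumes (TR %.3f s, %d dummy)\n",
              d[1], d[2], d[3], d[4], x$volume_tr, sum(x$dummy)))
  invisible(x)
}

#' Affine for a grid centered at the origin
#' @param dims integer length 3.
#' @param voxel_size numeric length 3, mm.
#' @return 4 x 4 matrix mapping 1-based voxel indices to mm.
#' @export
centered_affine <- function(dims, voxel_size) {
  voxel_size <- rep_len(voxel_size, 3)
  A <- diag(4)
  diag(A)[1:3] <- voxel_size
  A[1:3, 4] <- -voxel_size * (dims + 1) / 2
  A
}

#' Split an interleaved series into its two conditions
#'
#' Dummy volumes are excluded; each returned series preserves the original
#' temporal order and carries its original volume indices in
#' `$volume_index`. When the two conditions have unequal counts the longer
#' one is truncated to the shorter with a warning.
#'
#' @param series a `volume_series`.
#' @param conditions character length 2; the pair of condition labels to
#'   extract (default the functional nulled/control pair).
#' @return A list with elements named after `conditions`.
#' @export
split_conditions <- function(series, conditions = c("nulled", "control")) {
  keep <- !series$dummy
  idx <- lapply(conditions, function(cc) which(series$schedule == cc & keep))
  names(idx) <- conditions
  if (any(lengths(idx) == 0))
    stop("condition missing from schedule: ",
         paste(conditions[lengths(idx) == 0], collapse = ", "))
  n <- min(lengths(idx))
  if (any(lengths(idx) != n)) {
    warning(sprintf("unequal condition counts; truncated to %d volumes each", n))
    idx <- lapply(idx, function(i) i[seq_len(n)])
  }
  out <- lapply(idx, function(i) {
    s <- series
    s$data <- series$data[, , , i, drop = FALSE]
    s$schedule <- series$schedule[i]
    s$dummy <- series$dummy[i]
    s$volume_index <- series$volume_index[i]
    s
  })
  out
}

#' Paired blood-volume (VAPER-style) and BOLD series
#'
#' Holds the dynamic-division contrast `vaper[v, t] = (C - N) / C` and the
#' accompanying control (BOLD) series at the paired effective TR.
#'
#' @seealso [compute_vaper()]
#' @param vaper,bold 4D arrays (x, y, z, pair).
#' @param volume_tr volume TR in seconds.
#' @param pair_volumes integer matrix, pairs x 2, original volume indices
#'   (nulled, control).
#' @param affine voxel-to-mm affine.
#' @param voxel_size numeric length 3.
#' @return An object of class `paired_series` with `effective_tr ==
#'   2 * volume_tr`.
#' @export
paired_series <- function(vaper, bold, volume_tr, pair_volumes, affine,
                          voxel_size) {
  structure(list(vaper = vaper, bold = bold,
                 volume_tr = volume_tr,
                 effective_tr = effective_timing(volume_tr),
                 pair_volumes = pair_volumes,
                 affine = affine, voxel_size = voxel_size),
            class = "paired_series")
}

#' @export
print.paired_series <- function(x, ...) {
  cat(sprintf("<paired_series> %d pairs, effective TR %.3f s\n",
              dim(x$vaper)[4], x$effective_tr))
  invisible(x)
}

#' Dynamic-division blood-volume contrast from paired conditions
#'
#' Each blood-nulled volume is subtracted from the temporally nearest
#' control volume of its interleave cycle, and the difference divided by
#' that control volume:
#' `vaper = (control - nulled) / control`. The division removes the
#' multiplicative T2*-weighted (BOLD) factor shared by the two conditions,
#' so the result is positive where blood signal was suppressed. The control
#' series itself is returned unchanged as the conventional BOLD signal.
#'
#' Voxels where the control signal is not positive yield `NA`; their
#' fraction is reported in a message.
#'
#' @param control,nulled condition series from [split_conditions()].
#' @return A `paired_series`.
#' @export
compute_vaper <- function(control, nulled) {
  nc <- dim(control$data)[4]; nn <- dim(nulled$data)[4]
  if (nc != nn) stop("control and nulled series must have equal pair counts")
  C <- control$data
  N <- nulled$data
  bad <- !is.na(C) & C <= 0
  if (any(bad)) {
    C[bad] <- NA_real_
    message(sprintf("compute_vaper: %.3f%% of voxel-time values had nonpositive control signal; set missing",
                    100 * mean(bad)))
  }
  vap <- (C - N) / C
  paired_series(vap, control$data, control$volume_tr,
                pair_volumes = cbind(nulled = nulled$volume_index,
                                     control = control$volume_index),
                affine = control$affine, voxel_size = control$voxel_size)
}

#' MT-weighted anatomical contrast
#'
#' Computes the magnetization-transfer saturation contrast
#' `(ctrl - mt) / mt` from the mean control and mean MT-prepared volumes.
#' The ratio removes the shared T2*-weighted EPI factor; values are higher
#' where the macromolecular proton fraction is higher (white matter above
#' gray matter).
#'
#' @param ctrl_mean,mt_mean 3D arrays: temporal means over non-censored
#'   volumes of each condition.
#' @return A 3D array; `NA` where `mt_mean <= 0`.
#' @export
compute_mt_anatomical <- function(ctrl_mean, mt_mean) {
  stopifnot(identical(dim(ctrl_mean), dim(mt_mean)))
  out <- (ctrl_mean - mt_mean) / mt_mean
  out[!is.na(mt_mean) & mt_mean <= 0] <- NA_real_
  out
}

#' Effective sampling interval of an interleaved acquisition
#'
#' With two interleaved conditions each contrast time point consumes two
#' volume TRs, so the effective TR is doubled.
#'
#' @param volume_tr volume TR in seconds, > 0.
#' @return `2 * volume_tr` in seconds.
#' @export
effective_timing <- function(volume_tr) {
  if (!is.numeric(volume_tr) || length(volume_tr) != 1 || volume_tr <= 0)
    stop("volume_tr must be a positive scalar")
  2 * volume_tr
}
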