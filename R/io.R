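#' Write and read an interleaved volume series as NIfTI + JSON sidecar
#'
#' The 4D data go to `<prefix>.nii.gz`; the condition schedule, dummy
#' flags, timing, and the exact voxel-to-mm affine go to `<prefix>.json`.
#'
#' @param series a `volume_series`.
#' @param prefix output path prefix (no extension).
#' @return Invisibly, the NIfTI path.
#' @export
write_volume_series <- function(series, prefix) {
  nii_path <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, series$volume_tr)
  RNifti::writeNifti(img, nii_path)
  side <- list(schedule = series$schedule, dummy = series$dummy,
               volume_tr = series$volume_tr, te = series$te,
               voxel_size = series$voxel_size,
               affine = as.vector(series$affine))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(nii_path)
}

#' @rdname write_volume_series
#' @export
read_volume_series <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  volume_series(array(as.numeric(img), dim(img)),
                voxel_size = side$voxel_size,
                volume_tr = side$volume_tr,
                schedule = side$schedule,
                dummy = side$dummy, te = side$te,
                affine = matrix(side$affine, 4, 4))
}

#' Write and read motion parameters as TSV
#'
#' Six columns: 3 translations in mm and 3 rotations in degrees, one row
#' per volume.
#'
#' @param motion a `motion_trace`.
#' @param path TSV path.
#' @return Invisibly the path; the reader returns a `motion_trace`.
#' @export
write_motion_tsv <- function(motion, path) {
  df <- as.data.frame(motion$params)
  names(df) <- c("trans_x", "trans_y", "trans_z",
                 "rot_x", "rot_y", "rot_z")
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  motion_trace(as.matrix(df))
}

#' Write a censor mask as a one-column 0/1 text file
#'
#' @param censor_mask a `censor_mask`.
#' @param path output path.
#' @return Invisibly the path.
#' @export
write_censor_mask <- function(censor_mask, path) {
  writeLines(as.character(as.integer(censor_mask$keep)), path)
  invisible(path)
}

#' Write and read a surface mesh as JSON
#'
#' Lightweight GIFTI-style interchange: vertex coordinates and 1-based
#' triangle indices.
#'
#' @param mesh a `surface_mesh`.
#' @param path file path.
#' @return Invisibly the path; the reader returns a `surface_mesh`.
#' @export
write_surface_json <- function(mesh, path) {
  jsonlite::write_json(list(vertices = mesh$vertices,
                            triangles = mesh$triangles),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_surface_json
#' @export
read_surface_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  surface_mesh(x$vertices, x$triangles)
}

#' Write a laminar mesh as JSON (one coordinate array per depth)
#' @param lmesh a `laminar_mesh`.
#' @param path file path.
#' @return Invisibly the path; the reader returns a `laminar_mesh`.
#' @export
write_laminar_mesh_json <- function(lmesh, path) {
  jsonlite::write_json(
    list(triangles = lmesh$base$triangles,
         depth_fractions = lmesh$depth_fractions,
         coords = lapply(seq_len(lmesh$n_depths),
                         function(d) lmesh$coords[, d, ])),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_laminar_mesh_json
#' @export
read_laminar_mesh_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # equal-sized per-depth matrices may simplify to one depth x vertex x 3 array
  if (is.array(x$coords)) {
    D <- dim(x$coords)[1]
    nv <- dim(x$coords)[2]
    coords <- aperm(x$coords, c(2, 1, 3))
  } else {
    D <- length(x$coords)
    nv <- nrow(x$coords[[1]])
    coords <- array(0, c(nv, D, 3))
    for (d in seq_len(D)) coords[, d, ] <- x$coords[[d]]
  }
  base <- surface_mesh(coords[, 1, ], x$triangles)
  laminar_mesh(base, coords, x$depth_fractions)
}

#' Write an FCS map as long-format TSV
#'
#' Columns `vertex`, `depth`, `value`; `NA` rows (outside the map's
#' network) are omitted.
#'
#' @param map an `fcs_map`.
#' @param path TSV path.
#' @return Invisibly the path.
#' @export
write_fcs_tsv <- function(map, path) {
  v <- map$values
  df <- data.frame(vertex = rep(seq_len(nrow(v)), ncol(v)),
                   depth = rep(seq_len(ncol(v)), each = nrow(v)),
                   value = as.vector(v))
  df <- df[is.finite(df$value), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a laminar profile table as TSV
#' @param profile tibble from [extract_profile()].
#' @param path TSV path.
#' @return Invisibly the path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ground truth of a synthetic session as JSON
#' @param truth a `ground_truth`.
#' @param path file path.
#' @return Invisibly the path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(list(labels = truth$labels,
                            peak_depth = truth$peak_depth,
                            network_masks = truth$network_masks,
                            latent_signals = truth$latent_signals),
                       path, digits = NA)
  invisible(path)
}

#' Write a reliability report as JSON
#' @param rel a `laminar_reliability`.
#' @param path file path.
#' @param extra optional named list of configuration values to include.
#' @return Invisibly the path.
#' @export
write_reliability_json <- function(rel, path, extra = list()) {
  jsonlite::write_json(c(list(dice_values = rel$dice_values,
                              null_dice = rel$null_dice,
                              t_stat = rel$t_stat, p_value = rel$p_value,
                              n_pairs = rel$n_pairs), extra),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
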