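#' Per-frame orientation-matrix series
#'
#' Container for a dose series of lattice orientations: one 3x3 matrix per
#' frame whose columns are the real-space cell vectors a, b, c in the lab
#' frame (Angstrom, beam along +z), plus the fluence axis, per-frame validity
#' flags and the symmetry context needed downstream.
#'
#' @param matrices 3x3xN array (or list of 3x3 matrices) of orientations.
#' @param fluence_axis numeric length N, accumulated fluence (e-/A^2) at the
#'   end of each frame; strictly increasing.
#' @param cell numeric length-6 cell constants the matrices must reproduce.
#' @param point_group rotational point-group symbol (see
#'   [point_group_rotations()]).
#' @param valid logical length N; defaults to all TRUE.
#' @return object of class `OrientationSeries`.
#' @export
orientation_series <- function(matrices, fluence_axis, cell, point_group = "1",
                               valid = NULL) {
  if (is.list(matrices)) {
    matrices <- array(unlist(matrices), dim = c(3, 3, length(matrices)))
  }
  stopifnot(length(dim(matrices)) == 3, all(dim(matrices)[1:2] == c(3, 3)))
  n <- dim(matrices)[3]
  stopifnot(length(fluence_axis) == n, all(diff(fluence_axis) > 0))
  if (is.null(valid)) valid <- rep(TRUE, n)
  stopifnot(length(valid) == n)
  structure(list(matrices = matrices, fluence_axis = as.numeric(fluence_axis),
                 valid = as.logical(valid), cell = as.numeric(cell),
                 point_group = point_group),
            class = "OrientationSeries")
}

#' @export
print.OrientationSeries <- function(x, ...) {
  n <- dim(x$matrices)[3]
  cat(sprintf("OrientationSeries: %d frames (%d valid), point group %s\n",
              n, sum(x$valid), x$point_group))
  cat(sprintf("  fluence %.4g .. %.4g e-/A^2\n",
              x$fluence_axis[1], x$fluence_axis[n]))
  cat(sprintf("  cell %.3f %.3f %.3f A, %.2f %.2f %.2f deg\n",
              x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5], x$cell[6]))
  invisible(x)
}

#' @export
length.OrientationSeries <- function(x) dim(x$matrices)[3]

#' Write / read orientation series as tab-separated text
#'
#' Format: one row per frame with columns `frame`, the nine matrix components
#' in column-major order (`ax ay az bx by bz cx cy cz`), `fluence`, `valid`.
#'
#' @param series an `OrientationSeries`.
#' @param path file path.
#' @rdname orientation_table
#' @export
write_orientation_table <- function(series, path) {
  n <- length(series)
  comp <- t(array(series$matrices, c(9, n))) # column-major components per frame
  colnames(comp) <- c("ax", "ay", "az", "bx", "by", "bz", "cx", "cy", "cz")
  df <- data.frame(frame = seq_len(n), comp,
                   fluence = series$fluence_axis, valid = as.integer(series$valid))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param cell,point_group symmetry context to attach on read.
#' @rdname orientation_table
#' @export
read_orientation_table <- function(path, cell = NULL, point_group = "1") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("ax", "ay", "az", "bx", "by", "bz", "cx", "cy", "cz", "fluence")
  if (!all(need %in% names(df))) stop("orientation table missing required columns")
  n <- nrow(df)
  mats <- array(t(as.matrix(df[, need[1:9]])), dim = c(3, 3, n))
  valid <- if ("valid" %in% names(df)) df$valid > 0 else rep(TRUE, n)
  if (is.null(cell)) cell <- cell_constants(mats[, , 1])
  orientation_series(mats, df$fluence, cell, point_group, valid)
}

#' Simulate a beam-induced reorientation track
#'
#' Generates per-frame orientation matrices for a crystal whose consensus
#' orientation drifts smoothly about a fixed axis (angle proportional to
#' accumulated fluence), jitters randomly frame to frame, and optionally
#' undergoes an abrupt "crystal quake" after a critical fluence. Frame 1 is
#' the reference orientation (the cell matrix itself); the rotation applied
#' to frame i uses the fluence accumulated before that frame,
#' `(i - 1) * fluence_per_frame`, so the reference frame carries zero dose.
#'
#' @param model a [crystal_model()].
#' @param traj a [bir_trajectory()].
#' @return an `OrientationSeries` with ground-truth attributes
#'   `gt_final_angle`, `gt_final_axis` (for jitter-free tracks) and
#'   `gt_quake_frame` (first frame carrying the quake rotation, or NA).
#' @export
simulate_orientation_track <- function(model, traj) {
  stopifnot(inherits(model, "CrystalModel"), inherits(traj, "BirTrajectory"))
  set.seed(model$seed)
  M0 <- cell_matrix(model$cell)
  n <- traj$n_frames
  fl_start <- (seq_len(n) - 1) * traj$fluence_per_frame
  quake_frame <- NA_integer_
  Rq <- diag(3)
  mats <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    R <- rotation_about_axis(traj$drift_axis, traj$drift_rate * fl_start[i])
    if (!is.null(traj$quake_fluence) && fl_start[i] >= traj$quake_fluence) {
      if (is.na(quake_frame)) {
        quake_frame <- i
        Rq <- rotation_about_axis(traj$quake_axis, traj$quake_angle)
      }
      R <- Rq %*% R
    }
    if (traj$jitter_sd > 0) {
      jax <- stats::rnorm(3)
      jang <- abs(stats::rnorm(1, 0, traj$jitter_sd))
      R <- rotation_about_axis(jax, jang) %*% R
    }
    mats[, , i] <- R %*% M0
  }
  out <- orientation_series(mats, (seq_len(n)) * traj$fluence_per_frame,
                            model$cell, model$point_group)
  gt <- relative_rotation(mats[, , 1], mats[, , n])
  attr(out, "gt_final_angle") <- gt$angle
  attr(out, "gt_final_axis") <- gt$axis
  attr(out, "gt_quake_frame") <- quake_frame
  out
}

#' Scramble an orientation track like ambiguous serial indexing
#'
#' Emulates the output of frame-by-frame auto-indexing of a dose series:
#' each frame's orientation is post-multiplied by a uniformly random proper
#' symmetry operation of the crystal's point group (indexing-setting
#' ambiguity), zero-mean Gaussian noise of standard deviation `noise_sd` is
#' added to every matrix component, and a fraction of frames is replaced by
#' random orientations (mis-indexed frames). Which frames were mis-indexed is
#' recorded in the attribute `gt_misindexed` for ground-truth comparisons;
#' the series' own `valid` flags are left TRUE (the analysis has to find
#' them).
#'
#' @param series an `OrientationSeries`.
#' @param model the [crystal_model()] providing cell and point group.
#' @param noise_sd additive component noise SD (Angstrom).
#' @param misindex_fraction fraction in \[0, 0.5) of frames to corrupt.
#' @param seed integer RNG seed.
#' @return an `OrientationSeries` with attribute `gt_misindexed`.
#' @export
scramble_indexing <- function(series, model, noise_sd = 0,
                              misindex_fraction = 0, seed = 1) {
  stopifnot(inherits(series, "OrientationSeries"))
  stopifnot(misindex_fraction >= 0, misindex_fraction < 0.5, noise_sd >= 0)
  ops <- point_group_rotations(model$point_group)
  set.seed(seed)
  n <- length(series)
  mats <- series$matrices
  M0 <- cell_matrix(model$cell)
  pick <- sample.int(length(ops), n, replace = TRUE)
  for (i in seq_len(n)) mats[, , i] <- mats[, , i] %*% ops[[pick[i]]]
  bad <- rep(FALSE, n)
  n_bad <- floor(misindex_fraction * n)
  if (n_bad > 0) {
    idx <- sample.int(n, n_bad)
    bad[idx] <- TRUE
    for (i in idx) mats[, , i] <- random_rotation() %*% M0
  }
  if (noise_sd > 0) mats <- mats + array(stats::rnorm(9 * n, 0, noise_sd), c(3, 3, n))
  out <- orientation_series(mats, series$fluence_axis, series$cell,
                            model$point_group, series$valid)
  attr(out, "gt_misindexed") <- bad
  out
}
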