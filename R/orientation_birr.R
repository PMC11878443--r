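#' Resolve indexing-setting ambiguity along a dose series
#'
#' Serial indexing of a still dose series may return, frame by frame, any of
#' the symmetry-equivalent settings of the same physical orientation. Taking
#' the earliest determined orientation as ground truth, each subsequent frame
#' is replaced by the symmetry-equivalent candidate `M %*% S` (S a proper
#' point-group operator) nearest the previous, already-corrected frame.
#' "Nearest" is the Frobenius norm of the component difference (a
#' relative-rotation-angle metric is available as an alternative); ties are
#' broken by the lowest operator index.
#'
#' @param series an `OrientationSeries`.
#' @param ops list of integer operator matrices, e.g. from
#'   [point_group_rotations()]; defaults to the series' own point group.
#' @param metric `"frobenius"` (default) or `"angle"`.
#' @return the corrected `OrientationSeries`.
#' @export
disambiguate <- function(series, ops = NULL, metric = c("frobenius", "angle")) {
  stopifnot(inherits(series, "OrientationSeries"))
  metric <- match.arg(metric)
  if (is.null(ops)) ops <- point_group_rotations(series$point_group)
  n <- length(series)
  if (!series$valid[1]) stop("frame 1 must be valid to anchor disambiguation")
  mats <- series$matrices
  prev <- mats[, , 1]
  for (i in seq_len(n)[-1]) {
    M <- mats[, , i]
    best <- 1L
    bestd <- Inf
    for (j in seq_along(ops)) {
      cand <- M %*% ops[[j]]
      d <- if (metric == "frobenius") {
        sum((cand - prev)^2)
      } else {
        relative_rotation(prev, cand)$angle
      }
      if (d < bestd - 1e-12) {
        bestd <- d
        best <- j
      }
    }
    mats[, , i] <- M %*% ops[[best]]
    if (series$valid[i]) prev <- mats[, , i]
  }
  series$matrices <- mats
  series
}

#' Reject likely mis-indexed frames
#'
#' A frame is flagged as mis-indexed when, for at least one of the nine
#' orientation-matrix components, its value differs from the corresponding
#' component of BOTH the previous and the next frame by more than
#' `sigma_k` standard deviations -- where the SD is computed per component
#' index over all frames of the dataset (one pass, outlier candidates
#' included). The first and last frames use their single neighbor for both
#' comparisons. Flagged frames have `valid` set to FALSE and are excluded
#' from downstream computation.
#'
#' @param series an `OrientationSeries` with at least 3 valid frames
#'   (otherwise returned unchanged with a warning).
#' @param sigma_k multiple of the per-component SD (default 2).
#' @return the `OrientationSeries` with updated `valid` flags and attribute
#'   `rejected` (indices flagged by this call).
#' @export
reject_misindexed <- function(series, sigma_k = 2) {
  stopifnot(inherits(series, "OrientationSeries"), sigma_k > 0)
  n <- length(series)
  if (sum(series$valid) < 3) {
    warning("fewer than 3 valid frames; mis-index rejection skipped")
    attr(series, "rejected") <- integer(0)
    return(series)
  }
  comp <- t(array(series$matrices, c(9, n)))  # n x 9
  sigma <- apply(comp, 2, stats::sd)
  prev_i <- c(2L, seq_len(n - 1))   # endpoints use their single neighbor twice
  next_i <- c(2:n, n - 1L)
  dprev <- abs(comp - comp[prev_i, , drop = FALSE])
  dnext <- abs(comp - comp[next_i, , drop = FALSE])
  thr <- matrix(sigma_k * sigma, n, 9, byrow = TRUE)
  flag <- rowSums(dprev > thr & dnext > thr) > 0
  rejected <- which(flag & series$valid)
  series$valid[rejected] <- FALSE
  attr(series, "rejected") <- rejected
  series
}

#' Net beam-induced rotation of a dose series
#'
#' For every valid frame, computes the proper rotation relating it to the
#' first valid frame (orthogonal Procrustes, see [relative_rotation()]) and
#' its axis-angle decomposition, plus the angular change of each unit-cell
#' vector (columns a, b, c) from its initial direction. The final axis/angle
#' is taken at the last valid frame at or before `max_fluence`. Relative
#' rotations between consecutive valid frames are also recorded (the basis
#' for quake detection).
#'
#' @param series a disambiguated, outlier-rejected `OrientationSeries` with
#'   at least 2 valid frames.
#' @param max_fluence report the net rotation at the last valid frame at or
#'   before this fluence (default: end of series).
#' @return object of class `RotationSummary`: list with `frame` (valid frame
#'   indices), `fluence`, `per_frame_angle` (degrees vs frame 0),
#'   `per_vector_angles` (n x 3, degrees), `step_angle` / `step_fluence`
#'   (consecutive-frame rotations), `final_angle`, `final_axis`,
#'   `final_fluence`.
#' @export
net_rotation <- function(series, max_fluence = Inf) {
  stopifnot(inherits(series, "OrientationSeries"))
  vi <- which(series$valid)
  if (length(vi) < 2) stop("need at least 2 valid frames")
  M0 <- series$matrices[, , vi[1]]
  nv <- length(vi)
  ang <- numeric(nv)
  axes <- matrix(0, nv, 3)
  pv <- matrix(0, nv, 3)
  step_angle <- numeric(nv - 1)
  for (j in seq_len(nv)) {
    Mi <- series$matrices[, , vi[j]]
    rr <- relative_rotation(M0, Mi)
    ang[j] <- rr$angle
    axes[j, ] <- rr$axis
    for (v in 1:3) pv[j, v] <- angle_between(M0[, v], Mi[, v])
    if (j > 1) {
      step_angle[j - 1] <- relative_rotation(series$matrices[, , vi[j - 1]], Mi)$angle
    }
  }
  fl <- series$fluence_axis[vi]
  fin <- max(which(fl <= max_fluence))
  if (!is.finite(fin) || fin < 1) stop("no valid frame at or before max_fluence")
  structure(list(frame = vi, fluence = fl,
                 per_frame_angle = ang, per_frame_axis = axes,
                 per_vector_angles = pv,
                 step_angle = step_angle, step_fluence = fl[-1],
                 final_angle = ang[fin], final_axis = axes[fin, ],
                 final_fluence = fl[fin]),
            class = "RotationSummary")
}

#' @export
print.RotationSummary <- function(x, ...) {
  cat(sprintf("RotationSummary: %d valid frames, fluence up to %.4g e-/A^2\n",
              length(x$frame), max(x$fluence)))
  cat(sprintf("  net rotation %.4f deg about (%.3f, %.3f, %.3f) at %.4g e-/A^2\n",
              x$final_angle, x$final_axis[1], x$final_axis[2], x$final_axis[3],
              x$final_fluence))
  invisible(x)
}

#' Detect a crystal quake
#'
#' Finds the largest frame-to-frame consensus rotation in a
#' [net_rotation()] summary; if it exceeds `threshold`, returns the fluence
#' at which it occurred (the fluence of the later frame of the pair),
#' otherwise `NULL`.
#'
#' @param summary a `RotationSummary`.
#' @param threshold degrees per frame step.
#' @return fluence (e-/A^2) of the quake, or NULL if none exceeds threshold.
#' @export
detect_quake <- function(summary, threshold = 1) {
  stopifnot(inherits(summary, "RotationSummary"))
  if (length(summary$step_angle) < 2) return(NULL)
  i <- which.max(summary$step_angle)
  if (summary$step_angle[i] > threshold) summary$step_fluence[i] else NULL
}

#' Refine an orientation against observed spot positions
#'
#' Given a candidate orientation within a few degrees of the truth, predicts
#' the detector positions of near-Ewald-sphere reflections, assigns each
#' observed spot to the nearest prediction within `capture_radius` pixels,
#' back-projects matched observations onto the Ewald sphere, and solves for
#' the proper rotation minimizing the squared residuals between predicted
#' and observed scattering vectors (Kabsch). Iterates until the update angle
#' falls below `tol_deg` or `max_iter` is reached. With fewer than 3 matched
#' spots the refinement is refused and the candidate returned with attribute
#' `refined = FALSE`.
#'
#' @param spots a `SpotTable` of observed peaks.
#' @param candidate 3x3 candidate orientation matrix.
#' @param model a [crystal_model()] (cell, resolution range, rocking width).
#' @param det a [detector_geometry()].
#' @param capture_radius assignment radius in pixels (default 10).
#' @param max_iter,tol_deg iteration controls.
#' @return refined 3x3 orientation matrix with attributes `refined`
#'   (logical), `n_matched`, `iterations`.
#' @export
refine_orientation <- function(spots, candidate, model, det,
                               capture_radius = 10, max_iter = 10,
                               tol_deg = 1e-4) {
  stopifnot(nrow(spots) >= 1)
  refl <- reflection_table(model)
  lam <- det$wavelength
  M <- candidate
  n_matched <- 0L
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    pred <- predict_spots(model, M, det, refl)
    if (nrow(pred) == 0) break
    # assign each observed spot to nearest prediction
    dmat <- outer(spots$row, pred$row, "-")^2 + outer(spots$col, pred$col, "-")^2
    j <- apply(dmat, 1, which.min)
    ok <- sqrt(dmat[cbind(seq_len(nrow(spots)), j)]) <= capture_radius
    n_matched <- sum(ok)
    if (n_matched < 3) break
    # back-project both predicted and observed pixel positions onto the
    # Ewald sphere through the same mapping, so residuals reflect only the
    # orientation error (not each reflection's excitation error)
    backproject <- function(rowpx, colpx) {
      x <- (colpx - det$beam_center[2]) * det$pixel_size
      y <- (rowpx - det$beam_center[1]) * det$pixel_size
      kd <- rbind(x, y, rep(det$distance, length(x)))
      kd <- kd / matrix(sqrt(colSums(kd^2)), 3, length(x), byrow = TRUE) / lam
      kd - c(0, 0, 1 / lam)
    }
    q_pred <- backproject(pred$row[j[ok]], pred$col[j[ok]])
    q_obs <- backproject(spots$row[ok], spots$col[ok])
    # Kabsch: rotation R minimizing ||R q_pred - q_obs||
    H <- q_obs %*% t(q_pred)
    sv <- svd(H)
    dsign <- sign(det(sv$u %*% t(sv$v)))
    R <- sv$u %*% diag(c(1, 1, dsign)) %*% t(sv$v)
    M <- R %*% M
    if (axis_angle(R)$angle < tol_deg) break
  }
  refined <- n_matched >= 3
  if (!refined) {
    warning("refinement refused: fewer than 3 spots matched within capture radius")
    M <- candidate
  }
  structure(M, refined = refined, n_matched = n_matched, iterations = iters)
}
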