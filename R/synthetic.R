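#' Crystal model for synthetic dose series
#'
#' Parameters of the warping-crystal ground-truth model: unit cell, rotational
#' point group, rendered resolution range, per-reflection base intensities,
#' the resolution-dependent decay rate of the damage law
#' `I(d, D) = I0 * exp(-alpha * D / d^2)` (D = accumulated fluence in e-/A^2,
#' d = reflection d-spacing in Angstrom), and the mosaic rocking half-width
#' that decides which reflections are excited on a still frame.
#'
#' @param cell numeric length-6 cell constants (a, b, c in Angstrom; alpha,
#'   beta, gamma in degrees), all positive.
#' @param point_group rotational point-group symbol (see
#'   [point_group_rotations()]).
#' @param resolution_limit minimum d-spacing rendered (Angstrom).
#' @param base_intensities optional named numeric vector of per-reflection
#'   scale factors keyed `"h,k,l"`; reflections without an entry (or all of
#'   them, when NULL) get reproducible log-normal intensities drawn from
#'   `seed`.
#' @param decay_rate alpha >= 0, in A^2 per (e-/A^2).
#' @param rocking_halfwidth mosaic excitation half-width in degrees,
#'   0 < value < 5.
#' @param seed integer RNG seed for everything derived from the model.
#' @return object of class `CrystalModel`.
#' @export
crystal_model <- function(cell = c(10.2, 14.8, 6.9, 90, 90, 90),
                          point_group = "222",
                          resolution_limit = 1.0,
                          base_intensities = NULL,
                          decay_rate = 2.0,
                          rocking_halfwidth = 0.3,
                          seed = 1L) {
  stopifnot(length(cell) == 6, all(cell > 0), resolution_limit > 0,
            decay_rate >= 0, rocking_halfwidth > 0, rocking_halfwidth < 5)
  point_group_rotations(point_group) # validate symbol early
  structure(list(cell = as.numeric(cell), point_group = point_group,
                 resolution_limit = resolution_limit,
                 base_intensities = base_intensities,
                 decay_rate = decay_rate,
                 rocking_halfwidth = rocking_halfwidth,
                 seed = as.integer(seed)),
            class = "CrystalModel")
}

#' Beam-induced reorientation trajectory
#'
#' Ground-truth motion model for a dose series: smooth drift of the consensus
#' orientation (degrees per unit fluence about a fixed lab axis), per-frame
#' random jitter, and an optional abrupt reorientation ("crystal quake") at a
#' critical accumulated fluence.
#'
#' @param n_frames number of frames (>= 2).
#' @param fluence_per_frame fluence per frame, e-/A^2 (> 0).
#' @param drift_rate degrees of consensus rotation per e-/A^2 (>= 0).
#' @param drift_axis unit 3-vector, lab frame.
#' @param jitter_sd per-frame angular jitter SD in degrees (>= 0).
#' @param quake_fluence accumulated fluence at which the quake occurs
#'   (NULL for none).
#' @param quake_angle,quake_axis quake rotation (degrees, unit 3-vector).
#' @return object of class `BirTrajectory`.
#' @export
bir_trajectory <- function(n_frames = 150, fluence_per_frame = 0.01,
                           drift_rate = 0, drift_axis = c(0, 0, 1),
                           jitter_sd = 0, quake_fluence = NULL,
                           quake_angle = 0, quake_axis = c(1, 0, 0)) {
  stopifnot(n_frames >= 2, fluence_per_frame > 0, drift_rate >= 0,
            jitter_sd >= 0, quake_angle >= 0)
  norm_unit <- function(v, nm) {
    n <- sqrt(sum(v^2))
    if (abs(n - 1) > 1e-9) stop(sprintf("%s must be unit-norm within 1e-9", nm))
    v
  }
  drift_axis <- norm_unit(drift_axis, "drift_axis")
  if (!is.null(quake_fluence)) quake_axis <- norm_unit(quake_axis, "quake_axis")
  structure(list(n_frames = as.integer(n_frames),
                 fluence_per_frame = fluence_per_frame,
                 drift_rate = drift_rate, drift_axis = drift_axis,
                 jitter_sd = jitter_sd, quake_fluence = quake_fluence,
                 quake_angle = quake_angle, quake_axis = quake_axis),
            class = "BirTrajectory")
}

#' Detector geometry
#'
#' @param shape detector size in pixels, `c(rows, cols)`.
#' @param pixel_size pixel edge in mm.
#' @param distance sample-to-detector distance in mm.
#' @param wavelength beam wavelength in Angstrom (default: 200 kV electrons).
#' @param beam_center `c(row, col)` of the direct beam, in pixels (1-based).
#' @param beamstop_radius radius of the zeroed beamstop disc, pixels.
#' @return object of class `DetectorGeometry`.
#' @export
detector_geometry <- function(shape = c(512, 512), pixel_size = 0.055,
                              distance = 500, wavelength = electron_wavelength(200),
                              beam_center = (shape + 1) / 2,
                              beamstop_radius = 20) {
  stopifnot(all(shape > 0), pixel_size > 0, distance > 0, wavelength > 0,
            beamstop_radius >= 0, length(beam_center) == 2)
  if (any(beam_center < 1) || any(beam_center > shape)) {
    stop("beam_center must lie inside the detector")
  }
  structure(list(shape = as.integer(shape), pixel_size = pixel_size,
                 distance = distance, wavelength = wavelength,
                 beam_center = as.numeric(beam_center),
                 beamstop_radius = beamstop_radius),
            class = "DetectorGeometry")
}

#' Reflection table for a crystal model
#'
#' Enumerates all reciprocal-lattice points with d-spacing at or above the
#' model's resolution limit and attaches a reproducible base intensity to
#' each (log-normal, drawn from the model seed, unless supplied in the
#' model).
#'
#' @param model a [crystal_model()].
#' @return data.frame with columns h, k, l, d (Angstrom), base_intensity.
#' @export
reflection_table <- function(model) {
  M0 <- cell_matrix(model$cell)
  Bstar <- t(solve(M0))
  dmin <- model$resolution_limit
  hmax <- pmax(1L, ceiling(model$cell[1:3] / dmin))
  g <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2], l = -hmax[3]:hmax[3])
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  q <- Bstar %*% t(as.matrix(g))
  d <- 1 / sqrt(colSums(q^2))
  keep <- d >= dmin
  g <- g[keep, ]
  d <- d[keep]
  key <- paste(g$h, g$k, g$l, sep = ",")
  set.seed(model$seed)
  ord <- order(key) # deterministic assignment independent of enumeration order
  I0 <- numeric(length(key))
  I0[ord] <- stats::rlnorm(length(key), meanlog = log(5e3), sdlog = 0.5)
  if (!is.null(model$base_intensities)) {
    hit <- key %in% names(model$base_intensities)
    I0[hit] <- model$base_intensities[key[hit]]
  }
  data.frame(h = g$h, k = g$k, l = g$l, d = d, base_intensity = I0,
             row.names = NULL)
}

#' Predicted detector positions of excited reflections
#'
#' For a given orientation, finds the reflections whose angular excitation
#' error is within the rocking half-width and projects them onto the
#' detector (gnomonic projection of the diffracted beam direction). The
#' angular excitation error of a reflection with reciprocal vector q is
#' approximated by `zeta / |q_perp|` where `zeta = -(q_z + lambda |q|^2 / 2)`
#' is the distance from the Ewald sphere along the beam and `q_perp` the
#' component normal to the beam.
#'
#' @param model a [crystal_model()].
#' @param orientation 3x3 matrix, columns = cell vectors in the lab frame.
#' @param det a [detector_geometry()].
#' @param refl optional precomputed [reflection_table()] (saves re-enumeration).
#' @return data.frame with h, k, l, d, base_intensity, row, col (fractional
#'   pixels), excitation_deg, rocking (triangular rocking-profile weight in
#'   (0, 1\]). Reflections projecting outside the detector are dropped.
#' @export
predict_spots <- function(model, orientation, det, refl = NULL) {
  if (is.null(refl)) refl <- reflection_table(model)
  Bstar <- t(solve(orientation))
  q <- Bstar %*% t(as.matrix(refl[, c("h", "k", "l")]))
  lam <- det$wavelength
  q2 <- colSums(q^2)
  qperp <- sqrt(q[1, ]^2 + q[2, ]^2)
  zeta <- -(q[3, ] + lam * q2 / 2)
  exc <- zeta / pmax(qperp, 1e-6) * 180 / pi
  sel <- abs(exc) < model$rocking_halfwidth & qperp > 1e-6
  if (!any(sel)) {
    return(cbind(refl[0, ], row = numeric(0), col = numeric(0),
                 excitation_deg = numeric(0), rocking = numeric(0)))
  }
  q <- q[, sel, drop = FALSE]
  kd <- q + c(0, 0, 1 / lam)        # diffracted wavevector (approx on sphere)
  # detector plane at z = distance; x -> col, y -> row
  colpx <- det$beam_center[2] + det$distance * kd[1, ] / kd[3, ] / det$pixel_size
  rowpx <- det$beam_center[1] + det$distance * kd[2, ] / kd[3, ] / det$pixel_size
  out <- cbind(refl[sel, ], row = rowpx, col = colpx,
               excitation_deg = exc[sel],
               rocking = 1 - abs(exc[sel]) / model$rocking_halfwidth)
  inside <- out$row >= 1 & out$row <= det$shape[1] &
    out$col >= 1 & out$col <= det$shape[2]
  out[inside, , drop = FALSE]
}

#' Render one still-diffraction frame
#'
#' Draws every excited reflection as a 2D Gaussian spot with integrated
#' intensity `base_intensity * exp(-alpha * fluence / d^2) * rocking`, adds a
#' flat background, applies Poisson noise, and zeroes the beamstop disc.
#'
#' @param model a [crystal_model()].
#' @param orientation 3x3 orientation matrix.
#' @param fluence accumulated fluence (e-/A^2) governing the decay factor.
#' @param det a [detector_geometry()].
#' @param seed integer seed for the Poisson noise.
#' @param background flat background level in counts (default 5).
#' @param spot_sigma Gaussian spot width in pixels (default 1.5).
#' @param poisson apply Poisson noise (default TRUE; FALSE returns the
#'   expected image).
#' @param refl optional precomputed [reflection_table()].
#' @return numeric matrix (rows x cols) of counts.
#' @export
render_diffraction_frame <- function(model, orientation, fluence, det, seed = 1L,
                                     background = 5, spot_sigma = 1.5,
                                     poisson = TRUE, refl = NULL) {
  stopifnot(fluence >= 0, background >= 0, spot_sigma > 0)
  pred <- predict_spots(model, orientation, det, refl)
  img <- matrix(background, det$shape[1], det$shape[2])
  if (nrow(pred) > 0) {
    Iint <- pred$base_intensity *
      exp(-model$decay_rate * fluence / pred$d^2) * pred$rocking
    w <- ceiling(4 * spot_sigma)
    for (s in seq_len(nrow(pred))) {
      r0 <- pred$row[s]; c0 <- pred$col[s]
      rr <- max(1, floor(r0 - w)):min(det$shape[1], ceiling(r0 + w))
      cc <- max(1, floor(c0 - w)):min(det$shape[2], ceiling(c0 + w))
      gr <- exp(-((rr - r0)^2) / (2 * spot_sigma^2))
      gc <- exp(-((cc - c0)^2) / (2 * spot_sigma^2))
      img[rr, cc] <- img[rr, cc] + Iint[s] / (2 * pi * spot_sigma^2) * outer(gr, gc)
    }
  }
  if (poisson) {
    set.seed(seed)
    img <- matrix(stats::rpois(length(img), img), nrow(img), ncol(img))
  }
  if (det$beamstop_radius > 0) {
    img[beamstop_mask(det)] <- 0
  }
  img
}

beamstop_mask <- function(det) {
  r <- outer((seq_len(det$shape[1]) - det$beam_center[1])^2,
             (seq_len(det$shape[2]) - det$beam_center[2])^2, "+")
  r <= det$beamstop_radius^2
}

#' Render a full diffraction dose series
#'
#' Renders one frame per orientation in `series`, with the decay law driven
#' by the fluence accumulated before each frame (frame 1 carries zero dose),
#' and wraps the result as a [frame_stack()]. Per-frame Poisson seeds are
#' derived from `model$seed` so the series is bit-reproducible.
#'
#' @param model a [crystal_model()].
#' @param series an `OrientationSeries` (e.g. from
#'   [simulate_orientation_track()]).
#' @param det a [detector_geometry()].
#' @param exposure_per_frame seconds per frame (metadata).
#' @param ... further arguments to [render_diffraction_frame()].
#' @return a `FrameStack`.
#' @export
render_dose_series <- function(model, series, det, exposure_per_frame = 1, ...) {
  n <- length(series)
  fpf <- diff(c(0, series$fluence_axis))
  refl <- reflection_table(model)
  data <- array(0, c(det$shape[1], det$shape[2], n))
  fl_start <- series$fluence_axis - fpf
  for (i in seq_len(n)) {
    data[, , i] <- render_diffraction_frame(
      model, series$matrices[, , i], fl_start[i], det,
      seed = model$seed + i, refl = refl, ...)
  }
  flux <- mean(fpf) / exposure_per_frame
  frame_stack(data, exposure_per_frame = exposure_per_frame, flux = flux,
              detector = det)
}

#' Generate an imaging-mode stack with migrating bend contours
#'
#' Emulates an imaging-mode movie of a bent nanocrystal: an elliptical
#' crystal mask of uniform brightness crossed by dark bands (bend contours)
#' whose positions migrate along the band normal at `band_params$speed`
#' pixels per e-/A^2 until the accumulated fluence reaches
#' `band_params$settle_fluence`, after which they are static. Gaussian
#' read-out noise is added.
#'
#' @param n_frames number of frames.
#' @param shape image size `c(rows, cols)`.
#' @param band_params list with `width` (Gaussian band sigma, px), `contrast`
#'   (fractional depth in (0, 1\]), `speed` (px per e-/A^2, >= 0),
#'   `settle_fluence` (e-/A^2), and optionally `offsets` (initial band
#'   center offsets, px).
#' @param fluence_per_frame fluence per frame (e-/A^2).
#' @param seed integer RNG seed.
#' @param noise_sd additive Gaussian noise SD (counts; 0 for noise-free).
#' @param base brightness of the crystal interior (counts).
#' @return a `FrameStack` with ground-truth attribute `gt_band_position`
#'   (matrix n_bands x n_frames of band-center offsets, px).
#' @export
generate_bend_contour_stack <- function(n_frames = 100, shape = c(128, 128),
                                        band_params = list(width = 3, contrast = 0.6,
                                                           speed = 20, settle_fluence = 0.5),
                                        fluence_per_frame = 0.01, seed = 1L,
                                        noise_sd = 1, base = 100) {
  stopifnot(n_frames >= 1, band_params$speed >= 0, band_params$contrast > 0,
            band_params$contrast <= 1, band_params$width > 0)
  set.seed(seed)
  rows <- seq_len(shape[1]); cols <- seq_len(shape[2])
  ctr <- (shape + 1) / 2
  # elliptical crystal footprint
  mask <- outer(((rows - ctr[1]) / (0.42 * shape[1]))^2,
                ((cols - ctr[2]) / (0.42 * shape[2]))^2, "+") <= 1
  offsets <- band_params$offsets
  if (is.null(offsets)) offsets <- c(-0.18, 0.02, 0.22) * shape[2]
  # signed distance from image center along the band normal (bands along rows)
  u <- matrix(rep(cols - ctr[2], each = shape[1]), shape[1], shape[2])
  fl_start <- (seq_len(n_frames) - 1) * fluence_per_frame
  moved <- pmin(fl_start, band_params$settle_fluence) * band_params$speed
  data <- array(0, c(shape[1], shape[2], n_frames))
  gt_pos <- matrix(0, length(offsets), n_frames)
  for (i in seq_len(n_frames)) {
    img <- matrix(0, shape[1], shape[2])
    img[mask] <- base
    for (b in seq_along(offsets)) {
      pos <- offsets[b] + moved[i]
      gt_pos[b, i] <- pos
      att <- 1 - band_params$contrast * exp(-((u - pos)^2) / (2 * band_params$width^2))
      img <- img * ifelse(mask, att, 1)
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          shape[1], shape[2])
      img <- pmax(img, 0)  # counts are non-negative
    }
    data[, , i] <- img
  }
  st <- frame_stack(data, exposure_per_frame = 1, flux = fluence_per_frame)
  attr(st, "gt_band_position") <- gt_pos
  st
}

#' Write a ground-truth manifest (key = value text)
#'
#' @param params named list of scalar parameters.
#' @param path output file.
#' @rdname manifest
#' @export
write_manifest <- function(params, path) {
  stopifnot(!is.null(names(params)), all(nzchar(names(params))))
  fmt <- vapply(params, function(v) paste(format(v, digits = 17), collapse = " "), "")
  writeLines(paste0(names(params), " = ", fmt), path)
  invisible(path)
}

#' @rdname manifest
#' @export
read_manifest <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  kv <- regmatches(ln, regexpr(" = ", ln), invert = TRUE)
  out <- lapply(kv, function(x) {
    v <- strsplit(trimws(x[2]), " +")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else paste(v, collapse = " ")
  })
  names(out) <- trimws(vapply(kv, `[`, "", 1))
  out
}
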