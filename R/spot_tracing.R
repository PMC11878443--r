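#' Detection image of a dose series
#'
#' Applies a Gaussian filter of one-pixel radius (`sigma = 1`) to every frame
#' and takes the pixelwise maximum-intensity projection over the stack. The
#' beamstop disc, where present in the stack's detector geometry, is replaced
#' by the background estimate (median of the projection outside the disc) so
#' it can never seed a detection.
#'
#' @param stack a `FrameStack` with at least one frame.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @return numeric matrix, the smoothed maximum projection.
#' @export
detection_image <- function(stack, sigma = 1) {
  stopifnot(inherits(stack, "FrameStack"), n_frames(stack) >= 1)
  n <- n_frames(stack)
  proj <- gaussian_blur(stack$data[, , 1], sigma)
  if (n > 1) {
    for (i in 2:n) proj <- pmax(proj, gaussian_blur(stack$data[, , i], sigma))
  }
  det <- stack$detector
  if (!is.null(det) && det$beamstop_radius > 0) {
    bs <- beamstop_mask(det)
    proj[bs] <- stats::median(proj[!bs])
  }
  proj
}

gaussian_blur <- function(img, sigma) {
  as.matrix(EBImage::gblur(img, sigma = sigma, radius = max(3, ceiling(3 * sigma))))
}

#' Table of detected Bragg peaks
#'
#' @param centers integer matrix (n x 2) of peak `(row, col)` positions.
#' @param mask_radius diamond (L1-ball) center-to-vertex distance in pixels.
#' @param resolution optional per-spot d-spacing (Angstrom).
#' @return object of class `SpotTable` (a data.frame with columns `id`,
#'   `row`, `col` and optionally `resolution`; `mask_radius` as attribute).
#' @export
spot_table <- function(centers, mask_radius = 25, resolution = NULL) {
  stopifnot(mask_radius >= 1)
  centers <- matrix(as.numeric(centers), ncol = 2)
  df <- data.frame(id = seq_len(nrow(centers)),
                   row = centers[, 1], col = centers[, 2])
  if (!is.null(resolution)) df$resolution <- resolution
  structure(df, mask_radius = mask_radius,
            class = c("SpotTable", "data.frame"))
}

#' Find Bragg spots on a detection image
#'
#' Thresholds the detection image at `threshold_factor` times the background,
#' groups suprathreshold pixels into connected components, takes the
#' intensity-weighted centroid of each component (rounded to the nearest
#' pixel, ties toward the lower index), and merges centers closer than
#' `mask_radius` pixels. When detector geometry is supplied, each spot is
#' annotated with the d-spacing implied by its radius from the beam center.
#'
#' @param det_image detection image (matrix), e.g. from [detection_image()].
#' @param threshold_factor multiple of background a pixel must exceed (> 1).
#' @param background scalar background level, or `"auto"` (the median of the
#'   image, excluding the beamstop disc when `geometry` is given).
#' @param mask_radius diamond mask radius for the resulting [spot_table()].
#' @param geometry optional [detector_geometry()] for resolution annotation
#'   and beamstop exclusion.
#' @param min_area smallest connected component (pixels) accepted as a spot;
#'   suppresses isolated noise exceedances of the threshold.
#' @return a `SpotTable` (possibly empty).
#' @export
find_spots <- function(det_image, threshold_factor = 1.25, background = "auto",
                       mask_radius = 25, geometry = NULL, min_area = 5) {
  stopifnot(threshold_factor > 1)
  bs <- if (!is.null(geometry) && geometry$beamstop_radius > 0) {
    beamstop_mask(geometry)
  } else {
    matrix(FALSE, nrow(det_image), ncol(det_image))
  }
  if (identical(background, "auto")) {
    background <- stats::median(det_image[!bs])
    if (!is.finite(background)) background <- 0
  }
  mask <- det_image > threshold_factor * background & !bs
  if (!any(mask)) return(spot_table(matrix(numeric(0), 0, 2), mask_radius))
  lab <- EBImage::bwlabel(mask)
  lab <- as.matrix(lab)
  area <- tabulate(lab[lab > 0])
  small <- which(area < min_area)
  if (length(small) > 0) lab[lab %in% small] <- 0L
  if (!any(lab > 0)) return(spot_table(matrix(numeric(0), 0, 2), mask_radius))
  idx <- which(lab > 0, arr.ind = TRUE)
  w <- det_image[lab > 0]
  comp <- lab[lab > 0]
  wsum <- tapply(w, comp, sum)
  wr <- tapply(w * idx[, 1], comp, sum) / wsum
  wc <- tapply(w * idx[, 2], comp, sum) / wsum
  wt <- as.numeric(wsum)
  centers <- cbind(round_half_down(wr), round_half_down(wc))
  merged <- merge_close_centers(centers, wt, mask_radius)
  res <- NULL
  if (!is.null(geometry)) res <- pixel_resolution(merged, geometry)
  spot_table(merged, mask_radius, resolution = res)
}

# round to nearest integer, exact .5 ties toward the lower index
round_half_down <- function(x) ceiling(x - 0.5)

# merge centers closer than radius: greedy single pass in descending weight
# order; a center landing within radius of an already-accepted one is folded
# into it (intensity-weighted), otherwise it seeds a new spot. Deterministic
# (ties in weight resolve by original component order).
merge_close_centers <- function(centers, weights, radius) {
  n <- nrow(centers)
  if (n < 2) return(centers)
  ord <- order(weights, decreasing = TRUE)
  acc_r <- acc_c <- acc_wr <- acc_wc <- acc_w <- numeric(0)
  for (i in ord) {
    if (length(acc_r) > 0) {
      d2 <- (acc_r - centers[i, 1])^2 + (acc_c - centers[i, 2])^2
      j <- which.min(d2)
      if (d2[j] < radius^2) {
        acc_wr[j] <- acc_wr[j] + weights[i] * centers[i, 1]
        acc_wc[j] <- acc_wc[j] + weights[i] * centers[i, 2]
        acc_w[j] <- acc_w[j] + weights[i]
        next
      }
    }
    acc_r <- c(acc_r, centers[i, 1]); acc_c <- c(acc_c, centers[i, 2])
    acc_wr <- c(acc_wr, weights[i] * centers[i, 1])
    acc_wc <- c(acc_wc, weights[i] * centers[i, 2])
    acc_w <- c(acc_w, weights[i])
  }
  cbind(round_half_down(acc_wr / acc_w), round_half_down(acc_wc / acc_w))
}

# d-spacing implied by a spot's radius from the beam center
pixel_resolution <- function(centers, det) {
  r_mm <- sqrt((centers[, 1] - det$beam_center[1])^2 +
                 (centers[, 2] - det$beam_center[2])^2) * det$pixel_size
  tth <- atan2(r_mm, det$distance)
  det$wavelength / (2 * sin(tth / 2))
}

# relative (row, col) offsets of the diamond |dr| + |dc| <= radius
diamond_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[abs(g$dr) + abs(g$dc) <= radius, ]
}

#' Integrate per-reflection intensity traces
#'
#' Sums detector counts inside a diamond-shaped mask (L1 ball of the table's
#' `mask_radius`) around every spot center, for every frame. Masks clipped at
#' the detector edge are summed over the in-bounds region and flagged in the
#' `clipped` attribute. Pixels claimed by several diamonds are assigned to
#' the nearer center (ties to the lower spot id).
#'
#' @param stack a `FrameStack`.
#' @param spots a non-empty `SpotTable`.
#' @return object of class `IntensityTraces`: list with `values` (n_spots x
#'   n_frames matrix), `fluence_axis`, `spot_id`, `normalization_state`
#'   (`"raw"`), `clipped` (per-spot edge flag) and `n_pixels` (pixels each
#'   spot actually owns after overlap resolution and edge clipping; the
#'   per-trace background expectation is `n_pixels * background`).
#' @export
integrate_traces <- function(stack, spots) {
  stopifnot(inherits(stack, "FrameStack"), nrow(spots) > 0)
  radius <- attr(spots, "mask_radius")
  off <- diamond_offsets(radius)
  d <- dim(stack$data)
  nsp <- nrow(spots)
  owner <- matrix(0L, d[1], d[2])      # spot id owning each pixel
  ownd <- matrix(Inf, d[1], d[2])      # L1 distance to that owner
  clipped <- logical(nsp)
  for (s in seq_len(nsp)) {
    rr <- spots$row[s] + off$dr
    cc <- spots$col[s] + off$dc
    inb <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
    if (!all(inb)) clipped[s] <- TRUE
    rr <- rr[inb]; cc <- cc[inb]
    l1 <- abs(off$dr[inb]) + abs(off$dc[inb])
    lin <- cbind(rr, cc)
    closer <- l1 < ownd[lin]
    owner[lin[closer, , drop = FALSE]] <- spots$id[s]
    ownd[lin[closer, , drop = FALSE]] <- l1[closer]
  }
  flat <- as.integer(owner)
  sel <- flat > 0
  vals <- matrix(0, nsp, d[3])
  for (i in seq_len(d[3])) {
    fr <- stack$data[, , i]
    sums <- rowsum(fr[sel], flat[sel])
    vals[as.integer(rownames(sums)), i] <- sums
  }
  n_pixels <- tabulate(flat[sel], nbins = nsp) # pixels each spot actually owns
  structure(list(values = vals, fluence_axis = stack$fluence_axis,
                 spot_id = spots$id, normalization_state = "raw",
                 clipped = clipped, n_pixels = n_pixels),
            class = "IntensityTraces")
}

#' @export
print.IntensityTraces <- function(x, ...) {
  cat(sprintf("IntensityTraces: %d spots x %d frames (%s)\n",
              nrow(x$values), ncol(x$values), x$normalization_state))
  invisible(x)
}

#' Summed trace of the brightest reflections
#'
#' Selects the brightest `top_fraction` of traces -- judged by each trace's
#' maximum intensity wherever in the series it occurs -- sums them framewise
#' and normalizes the sum to its maximum value.
#'
#' @param traces an `IntensityTraces`.
#' @param top_fraction fraction in (0, 1] of traces to keep (default 0.2,
#'   i.e. the brightest 20%); `ceiling(top_fraction * n_spots)` traces are
#'   used.
#' @return numeric vector of length n_frames with maximum exactly 1, with
#'   attribute `selected` (the spot ids summed).
#' @export
summed_trace <- function(traces, top_fraction = 0.2) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  v <- traces$values
  if (nrow(v) == 0) stop("no traces to sum")
  n_keep <- ceiling(top_fraction * nrow(v))
  mx <- apply(v, 1, max)
  keep <- order(mx, decreasing = TRUE)[seq_len(n_keep)]
  s <- colSums(v[keep, , drop = FALSE])
  if (max(s) <= 0) stop("summed trace is identically zero")
  out <- s / max(s)
  attr(out, "selected") <- traces$spot_id[keep]
  out
}

#' Derivative profile of a summed trace
#'
#' Finite differences of the (normalized) summed trace with respect to
#' fluence, evaluated on each frame interval, then binned into fluence bins
#' of width `bin_width`; the SD of derivative values within each bin is the
#' fluctuation statistic. The cumulative sum of `derivative * dfluence`
#' reconstructs `trace - trace[1]` exactly.
#'
#' @param trace numeric vector (normalized summed trace).
#' @param fluence_axis fluence at the end of each frame (same length).
#' @param bin_width fluence bin width in e-/A^2 (default 0.1).
#' @return object of class `DerivativeProfile`: list with `derivative`
#'   (length n-1), `mid_fluence` (interval midpoints), `dfluence`, `bins`
#'   (edges), `bin_sd`, `bin_mean`, `bin_n`.
#' @export
derivative_profile <- function(trace, fluence_axis, bin_width = 0.1) {
  n <- length(trace)
  if (n < 2) stop("need at least 2 frames for a derivative profile")
  stopifnot(length(fluence_axis) == n, bin_width > 0)
  df <- diff(fluence_axis)
  deriv <- diff(trace) / df
  mid <- fluence_axis[-n] + df / 2
  edges <- seq(0, max(fluence_axis) + bin_width, by = bin_width)
  bin <- findInterval(mid, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  bin_sd <- bin_mean <- rep(NA_real_, nb)
  bin_n <- integer(nb)
  for (b in seq_len(nb)) {
    v <- deriv[bin == b]
    bin_n[b] <- length(v)
    if (length(v) > 0) bin_mean[b] <- mean(v)
    bin_sd[b] <- if (length(v) > 1) stats::sd(v) else if (length(v) == 1) 0 else NA_real_
  }
  structure(list(derivative = deriv, mid_fluence = mid, dfluence = df,
                 bins = edges, bin_sd = bin_sd, bin_mean = bin_mean,
                 bin_n = bin_n),
            class = "DerivativeProfile")
}

#' Fluctuation summary across crystals
#'
#' Aggregates the per-bin derivative SDs of several crystals' profiles:
#' per-bin mean of `bin_sd` and its SD across profiles. All profiles must
#' share the same binning.
#'
#' @param profiles list of `DerivativeProfile` objects with identical bins.
#' @return data.frame with `bin_lo`, `bin_hi`, `mean_sd`, `sd_sd`,
#'   `n_profiles`.
#' @export
fluctuation_summary <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  nb <- length(profiles[[1]]$bins)
  for (p in profiles) {
    if (length(p$bins) != nb || max(abs(p$bins - profiles[[1]]$bins)) > 1e-9) {
      stop("profiles have mismatched fluence bins")
    }
  }
  m <- do.call(rbind, lapply(profiles, `[[`, "bin_sd"))
  data.frame(bin_lo = profiles[[1]]$bins[-nb],
             bin_hi = profiles[[1]]$bins[-1],
             mean_sd = colMeans(m, na.rm = TRUE),
             sd_sd = apply(m, 2, function(v) {
               v <- v[!is.na(v)]
               if (length(v) > 1) stats::sd(v) else 0
             }),
             n_profiles = colSums(!is.na(m)))
}
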