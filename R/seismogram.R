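#' Align imaging batches by normalized cross-correlation
#'
#' Imaging-mode dose series are often acquired as several movie batches with
#' slight stage drift between them. The integer-pixel shift between the last
#' frame of batch i and the first frame of batch i+1 is estimated by
#' normalized cross-correlation (FFT-based); shifts are accumulated and
#' applied to the later batches, and the batches concatenated in time. When
#' the correlation peak is below `floor` the shift is taken as zero with a
#' warning (featureless or pure-noise batches).
#'
#' @param batches list of `FrameStack`s with identical frame shapes (a single
#'   `FrameStack` is returned unchanged).
#' @param max_shift largest shift searched, pixels (default: a quarter of the
#'   smaller image dimension).
#' @param floor minimum correlation coefficient to accept a shift.
#' @return a concatenated `FrameStack` with attribute `batch_shifts`
#'   (n_batches x 2 matrix of cumulative (row, col) shifts applied).
#' @export
align_batches <- function(batches, max_shift = NULL, floor = 0.2) {
  if (inherits(batches, "FrameStack")) batches <- list(batches)
  stopifnot(length(batches) >= 1)
  shp <- dim(batches[[1]]$data)[1:2]
  for (b in batches) {
    if (!all(dim(b$data)[1:2] == shp)) stop("batches must share frame shape")
  }
  if (is.null(max_shift)) max_shift <- floor(min(shp) / 4)
  nb <- length(batches)
  shifts <- matrix(0L, nb, 2)   # cumulative displacement of each batch vs batch 1
  for (i in seq_len(nb - 1)) {
    ref <- batches[[i]]$data[, , n_frames(batches[[i]])]
    mov <- batches[[i + 1]]$data[, , 1]
    est <- estimate_shift(ref, mov, max_shift)
    if (est$peak < floor) {
      warning(sprintf("batch %d -> %d: correlation peak %.3f below floor; zero shift",
                      i, i + 1, est$peak))
      est$shift <- c(0L, 0L)
    }
    shifts[i + 1, ] <- shifts[i, ] + est$shift
  }
  total <- sum(vapply(batches, n_frames, 1L))
  data <- array(0, c(shp, total))
  at <- 0L
  for (i in seq_len(nb)) {
    d <- batches[[i]]$data
    for (k in seq_len(dim(d)[3])) {
      # undo the accumulated stage displacement
      data[, , at + k] <- shift_image(d[, , k], -shifts[i, ])
    }
    at <- at + dim(d)[3]
  }
  out <- frame_stack(data, batches[[1]]$exposure_per_frame, batches[[1]]$flux,
                     batches[[1]]$detector, batches[[1]]$temperature_label,
                     check_counts = FALSE)
  attr(out, "batch_shifts") <- shifts
  out
}

#' Estimate the integer displacement between two images
#'
#' FFT-based normalized cross-correlation of the mean-subtracted images.
#' Returns the displacement `shift` (row, col) such that `mov` is `ref`
#' translated by `shift`, together with the peak correlation coefficient
#' (in \[-1, 1\]).
#'
#' @param ref,mov numeric matrices of the same size.
#' @param max_shift largest displacement searched, pixels.
#' @return list with `shift` (integer length-2) and `peak`.
#' @export
estimate_shift <- function(ref, mov, max_shift = floor(min(dim(ref)) / 4)) {
  stopifnot(all(dim(ref) == dim(mov)))
  a <- ref - mean(ref)
  b <- mov - mean(mov)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(list(shift = c(0L, 0L), peak = 0))
  # circular cross-correlation: cc[lag] = sum_x a(x) b(x - lag)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) /
    length(a) / (na * nb)
  d <- dim(cc)
  lag_r <- c(0:(d[1] %/% 2), -((d[1] - 1) %/% 2):-1)
  lag_c <- c(0:(d[2] %/% 2), -((d[2] - 1) %/% 2):-1)
  ok <- outer(abs(lag_r) <= max_shift, abs(lag_c) <= max_shift, "&")
  cc[!ok] <- -Inf
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # peak at lag = -displacement (mov(x) = ref(x - s) peaks cc at lag = -s)
  list(shift = c(-lag_r[pk[1]], -lag_c[pk[2]]), peak = max(cc))
}

# translate an image by integer (row, col), padding with the image median
shift_image <- function(img, shift) {
  if (all(shift == 0)) return(img)
  d <- dim(img)
  out <- matrix(stats::median(img), d[1], d[2])
  src_r <- seq_len(d[1]) - shift[1]
  src_c <- seq_len(d[2]) - shift[2]
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Bin a stack in all three dimensions
#'
#' Mean-binning by an integer factor in time, rows and columns; trailing
#' remainder frames/pixels are dropped. The fluence axis is rebinned to the
#' mean fluence of each time bin.
#'
#' @param stack a `FrameStack`.
#' @param factor integer binning factor (default 5).
#' @return the binned `FrameStack`.
#' @export
bin_stack <- function(stack, factor = 5) {
  stopifnot(inherits(stack, "FrameStack"), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1) return(stack)
  d <- dim(stack$data)
  nd <- d %/% factor
  if (any(nd < 1)) stop("binning factor exceeds a stack dimension")
  crop <- stack$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                     seq_len(nd[3] * factor), drop = FALSE]
  a <- array(crop, c(factor, nd[1], factor * nd[2] * factor * nd[3]))
  a <- colMeans(a)                                   # rows binned
  a <- array(a, c(nd[1], factor, nd[2] * factor * nd[3]))
  a <- apply(a, c(1, 3), mean)                       # cols binned
  a <- array(a, c(nd[1], nd[2], factor, nd[3]))
  a <- apply(a, c(1, 2, 4), mean)                    # frames binned
  fl <- colMeans(matrix(stack$fluence_axis[seq_len(nd[3] * factor)], factor))
  out <- frame_stack(a, stack$exposure_per_frame * factor, stack$flux,
                     stack$detector, stack$temperature_label,
                     check_counts = FALSE)
  out$fluence_axis <- fl
  out
}

#' Zero-phase temporal low-pass filter
#'
#' Filters every pixel's time trace with a symmetric (zero-phase)
#' Hamming-windowed-sinc FIR kernel whose passband edge is `cutoff` cycles
#' per frame; the stopband (>= 20 dB attenuation, in practice > 40 dB)
#' begins at about 1.5x the cutoff. Edges are handled by replicate padding,
#' so constant signals pass unchanged and the filter is exactly linear.
#'
#' @param stack a `FrameStack`.
#' @param cutoff passband edge in cycles per frame, 0 < cutoff < 0.5.
#' @return the filtered `FrameStack`.
#' @export
temporal_lowpass <- function(stack, cutoff = 0.1) {
  stopifnot(inherits(stack, "FrameStack"), cutoff > 0, cutoff < 0.5)
  n <- n_frames(stack)
  kern <- lowpass_kernel(cutoff, n)
  half <- (length(kern) - 1) / 2
  if (n < 2 * half + 1) stop("too few frames for the filter order")
  d <- dim(stack$data)
  m <- matrix(stack$data, d[1] * d[2], d[3])
  padded <- cbind(m[, rep(1, half), drop = FALSE], m,
                  m[, rep(d[3], half), drop = FALSE])
  out <- matrix(0, d[1] * d[2], d[3])
  for (j in seq_along(kern)) {
    out <- out + kern[j] * padded[, j:(j + d[3] - 1), drop = FALSE]
  }
  res <- stack
  res$data <- array(out, d)
  res
}

# symmetric windowed-sinc low-pass kernel, unit DC gain; length capped by the
# series length (kernel must fit)
lowpass_kernel <- function(cutoff, n_frames) {
  trans <- 0.5 * cutoff                       # transition bandwidth
  L <- ceiling(3.3 / trans)
  if (L %% 2 == 0) L <- L + 1
  Lmax <- if (n_frames %% 2 == 1) n_frames else n_frames - 1
  L <- min(L, Lmax)
  if (L < 3) L <- 3
  half <- (L - 1) / 2
  t <- -half:half
  fc <- cutoff + trans / 2                    # cutoff at mid-transition
  h <- 2 * fc * sinc(2 * fc * t)
  w <- 0.54 + 0.46 * cos(pi * t / half)       # Hamming window
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Line seismogram (kymograph) of an imaging stack
#'
#' Samples pixel values along a fixed line segment -- typically spanning the
#' length of the crystal -- for every frame, by bilinear interpolation at
#' one-pixel steps, producing a position x frame array in which migrating
#' bend contours appear as sloped ridges.
#'
#' @param stack a `FrameStack`.
#' @param p0,p1 segment endpoints `c(row, col)`, inside the image.
#' @return object of class `Seismogram`: list with `line` (2x2 endpoint
#'   matrix), `positions` (distance along the line, pixels), `values`
#'   (position x frame matrix), `fluence_axis`.
#' @export
line_seismogram <- function(stack, p0, p1) {
  stopifnot(inherits(stack, "FrameStack"), length(p0) == 2, length(p1) == 2)
  d <- dim(stack$data)
  for (p in list(p0, p1)) {
    if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2]) {
      stop("line endpoints must lie inside the image")
    }
  }
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length line")
  ns <- floor(len) + 1
  tt <- seq(0, len, length.out = ns) / len
  rr <- p0[1] + tt * (p1[1] - p0[1])
  cc <- p0[2] + tt * (p1[2] - p0[2])
  vals <- matrix(0, ns, d[3])
  for (i in seq_len(d[3])) {
    vals[, i] <- bilinear_sample(stack$data[, , i], rr, cc)
  }
  structure(list(line = rbind(p0, p1), positions = tt * len, values = vals,
                 fluence_axis = stack$fluence_axis),
            class = "Seismogram")
}

bilinear_sample <- function(img, rr, cc) {
  d <- dim(img)
  r0 <- pmin(pmax(floor(rr), 1), d[1] - 1)
  c0 <- pmin(pmax(floor(cc), 1), d[2] - 1)
  fr <- rr - r0
  fc <- cc - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' @export
print.Seismogram <- function(x, ...) {
  cat(sprintf("Seismogram: %d positions x %d frames, line (%g, %g) -> (%g, %g)\n",
              nrow(x$values), ncol(x$values),
              x$line[1, 1], x$line[1, 2], x$line[2, 1], x$line[2, 2]))
  invisible(x)
}

#' Track a dark band across a seismogram
#'
#' Per-frame position of a single dark band (bend contour) along the sampled
#' line: the darkness profile `max(values) - values` is thresholded at half
#' its maximum (suppressing baseline noise) and the intensity-weighted
#' centroid of the remainder taken. Returns positions in the seismogram's
#' line coordinate (pixels from the first endpoint).
#'
#' @param s a `Seismogram` containing one dominant dark band.
#' @return numeric vector of band positions, one per frame, with attribute
#'   `fluence_axis`.
#' @export
track_band <- function(s) {
  stopifnot(inherits(s, "Seismogram"))
  pos <- apply(s$values, 2, function(v) {
    w <- max(v) - v
    w <- pmax(w - max(w) / 2, 0)
    sum(w * s$positions) / sum(w)
  })
  attr(pos, "fluence_axis") <- s$fluence_axis
  pos
}

#' Fluctuation trace of a seismogram
#'
#' For every line position the fluctuation amplitude at frame t is the
#' absolute difference between the pixel value and that position's temporal
#' mean; the fluctuation trace is the standard deviation of this amplitude
#' over all positions, per frame. Static scenes give an identically zero
#' trace; migrating contours elevate it while they move.
#'
#' @param s a `Seismogram` with at least 2 frames.
#' @return numeric vector (one value per frame), with attribute
#'   `fluence_axis`.
#' @export
fluctuation_trace <- function(s) {
  stopifnot(inherits(s, "Seismogram"), ncol(s$values) >= 2)
  tm <- rowMeans(s$values)
  amp <- abs(s$values - tm)
  out <- apply(amp, 2, stats::sd)
  attr(out, "fluence_axis") <- s$fluence_axis
  out
}
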