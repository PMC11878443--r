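#' Frame stack with fluence axis
#'
#' Container for a diffraction or imaging dose series: a 3D array of detector
#' counts indexed `[row, col, frame]`, the per-frame exposure, the beam flux,
#' and the derived cumulative-fluence axis. Fluence is assigned at the END of
#' each frame: `fluence_axis[i] = i * flux * exposure_per_frame`, i.e. the
#' intensity recorded on frame i reflects dose up to `fluence_axis[i]`.
#'
#' @param data 3D numeric array `[row, col, frame]` of counts (>= 0).
#' @param exposure_per_frame seconds per frame.
#' @param flux beam flux in e-/A^2/s.
#' @param detector optional [detector_geometry()].
#' @param temperature_label free-text label (e.g. "293 K").
#' @param check_counts verify non-negativity (disable for filtered stacks
#'   where FIR ringing may produce small negative excursions).
#' @return object of class `FrameStack`.
#' @export
frame_stack <- function(data, exposure_per_frame = 1, flux = 0.01,
                        detector = NULL, temperature_label = "293 K",
                        check_counts = TRUE) {
  if (length(dim(data)) == 2) data <- array(data, c(dim(data), 1))
  stopifnot(length(dim(data)) == 3, exposure_per_frame > 0, flux > 0)
  if (check_counts && min(data) < 0) stop("counts must be non-negative")
  n <- dim(data)[3]
  structure(list(data = data,
                 exposure_per_frame = exposure_per_frame,
                 flux = flux,
                 fluence_axis = seq_len(n) * flux * exposure_per_frame,
                 detector = detector,
                 temperature_label = temperature_label),
            class = "FrameStack")
}

#' @export
print.FrameStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("FrameStack: %d frames of %d x %d, %s\n", d[3], d[1], d[2],
              x$temperature_label))
  cat(sprintf("  flux %.4g e-/A^2/s, exposure %.3g s/frame, fluence up to %.4g e-/A^2\n",
              x$flux, x$exposure_per_frame, x$fluence_axis[d[3]]))
  invisible(x)
}

#' @export
dim.FrameStack <- function(x) dim(x$data)

#' Number of frames in a stack
#' @param stack a `FrameStack`.
#' @export
n_frames <- function(stack) dim(stack$data)[3]

#' Re-attach a flux and recompute the fluence axis
#' @param stack a `FrameStack`.
#' @param flux new flux (e-/A^2/s).
#' @export
set_flux <- function(stack, flux) {
  stopifnot(flux > 0)
  stack$flux <- flux
  stack$fluence_axis <- seq_len(n_frames(stack)) * flux * stack$exposure_per_frame
  stack
}

#' Calibrate beam flux from a flat-field image
#'
#' Converts mean detector counts on a gain-corrected flat-field exposure of
#' the parallel beam into flux, using the detector's counts-per-electron
#' conversion factor:
#' `flux = mean(flatfield) / counts_per_electron / pixel_area_at_specimen / exposure`.
#' The default conversion factor of 16 counts per electron event corresponds
#' to the Apollo direct electron detector.
#'
#' @param flatfield numeric matrix of counts (offset-corrected).
#' @param counts_per_electron detector conversion factor (counts per e-).
#' @param pixel_area_at_specimen area sampled by one pixel at the specimen
#'   plane, in A^2.
#' @param exposure exposure time in seconds.
#' @return flux in e-/A^2/s.
#' @export
calibrate_flux <- function(flatfield, counts_per_electron = 16,
                           pixel_area_at_specimen, exposure) {
  stopifnot(counts_per_electron > 0)
  if (pixel_area_at_specimen <= 0) stop("pixel_area_at_specimen must be positive")
  if (exposure <= 0) stop("exposure must be positive")
  mean(flatfield) / counts_per_electron / pixel_area_at_specimen / exposure
}

#' Read a frame stack from disk
#'
#' @param path an MRC file, or for `format = "smv-series"` a directory of
#'   `.img` files or a vector of file paths; frames are ordered by the
#'   numeric suffix in each filename.
#' @param format `"mrc"` or `"smv-series"`.
#' @param exposure_per_frame,flux metadata not carried by the file formats.
#' @param detector fallback [detector_geometry()] when headers lack geometry.
#' @return a `FrameStack`.
#' @export
read_stack <- function(path, format = c("mrc", "smv-series"),
                       exposure_per_frame = 1, flux = 0.01, detector = NULL) {
  format <- match.arg(format)
  if (format == "mrc") {
    m <- read_mrc(path)
    det <- detector
    if (is.null(det) && !is.na(m$pixel_size_mm)) {
      sh <- dim(m$data)[1:2]
      det <- detector_geometry(shape = sh, pixel_size = m$pixel_size_mm,
                               distance = 500)
    }
    return(frame_stack(m$data, exposure_per_frame, flux, det,
                       check_counts = FALSE))
  }
  files <- if (length(path) == 1 && dir.exists(path)) {
    list.files(path, pattern = "\\.img$", full.names = TRUE)
  } else {
    path
  }
  if (length(files) == 0) stop("no SMV frames found at ", path[1])
  suffix <- as.integer(sub(".*?([0-9]+)\\.img$", "\\1", files))
  if (anyNA(suffix)) stop("SMV filenames must carry a numeric suffix")
  files <- files[order(suffix)]
  frames <- lapply(files, read_smv)
  shp <- dim(frames[[1]]$data)
  if (!all(vapply(frames, function(f) all(dim(f$data) == shp), TRUE))) {
    stop("inconsistent frame shapes across SMV series")
  }
  data <- array(0, c(shp, length(frames)))
  for (i in seq_along(frames)) data[, , i] <- frames[[i]]$data
  det <- detector
  if (is.null(det)) det <- frames[[1]]$detector
  frame_stack(data, exposure_per_frame, flux, det)
}

#' Write a frame stack to disk
#'
#' MRC output is a single MRC2014 stack (mode 2, 32-bit float: exact for
#' integer counts below 2^24). SMV output is a series of single-frame ADSC
#' files `<prefix>_00001.img`, ... with unsigned 16-bit data and headers
#' carrying DIM, SIZE1/SIZE2, PIXEL_SIZE, DISTANCE, WAVELENGTH and
#' BEAM_CENTER_X/Y (mm).
#'
#' @param stack a `FrameStack`.
#' @param path output file (MRC) or path prefix (SMV series).
#' @param format `"mrc"` or `"smv-series"`.
#' @return invisibly, the file path(s) written.
#' @export
write_stack <- function(stack, path, format = c("mrc", "smv-series")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path))) {
    dir.create(dirname(path), recursive = TRUE)
  }
  if (format == "mrc") {
    pixmm <- if (!is.null(stack$detector)) stack$detector$pixel_size else NA_real_
    return(invisible(write_mrc(stack$data, path, pixel_size_mm = pixmm)))
  }
  det <- stack$detector
  if (is.null(det)) det <- detector_geometry(shape = dim(stack$data)[1:2])
  n <- n_frames(stack)
  files <- sprintf("%s_%05d.img", path, seq_len(n))
  for (i in seq_len(n)) write_smv(stack$data[, , i], files[i], det)
  invisible(files)
}

# ---- MRC2014 (minimal subset: modes 0, 1, 2, 6) -----------------------------

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 1024)
  npx <- nx * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = npx, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = npx, size = 2, endian = "little"),
    "2" = readBin(con, "numeric", n = npx, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = npx, size = 2, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode: ", mode))
  if (length(data) < npx) stop("truncated MRC data block")
  # MRC stores x (cols) fastest, then y (rows), then z
  arr <- aperm(array(as.numeric(data), c(nx, ny, nz)), c(2, 1, 3))
  px <- if (hdr[8] > 0 && cella[1] > 0) cella[1] / hdr[8] * 1e-7 else NA_real_
  list(data = arr, pixel_size_mm = px)
}

write_mrc <- function(arr, path, pixel_size_mm = NA_real_) {
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  d <- dim(arr)
  nx <- d[2]; ny <- d[1]; nz <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  px_ang <- if (is.na(pixel_size_mm)) 1 else pixel_size_mm * 1e7
  writeBin(as.integer(c(nx, ny, nz, 2L, 0L, 0L, 0L, nx, ny, nz)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(c(nx * px_ang, ny * px_ang, nz * px_ang, 90, 90, 90)),
           con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(arr), max(arr), mean(arr))), con, size = 4,
           endian = "little")
  writeBin(integer(2), con, size = 4, endian = "little")      # ispg, nsymbt
  writeBin(raw(100), con)                                      # extra
  writeBin(numeric(3), con, size = 4, endian = "little")       # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)             # little-endian stamp
  writeBin(as.numeric(stats::sd(arr)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")               # nlabl
  writeBin(raw(800), con)
  for (k in seq_len(nz)) {
    writeBin(as.numeric(t(arr[, , k])), con, size = 4, endian = "little")
  }
  path
}

# ---- SMV / ADSC -------------------------------------------------------------

write_smv <- function(frame, path, det) {
  if (any(frame < 0) || any(frame > 65535)) {
    warning("SMV is unsigned 16-bit; counts clamped to [0, 65535]")
    frame <- pmin(pmax(frame, 0), 65535)
  }
  hdr <- paste0(
    "{\nHEADER_BYTES= 512;\nDIM=2;\nBYTE_ORDER=little_endian;\n",
    "TYPE=unsigned_short;\n",
    sprintf("SIZE1=%d;\n", ncol(frame)),   # fast axis = cols
    sprintf("SIZE2=%d;\n", nrow(frame)),
    sprintf("PIXEL_SIZE=%.6f;\n", det$pixel_size),
    sprintf("DISTANCE=%.6f;\n", det$distance),
    sprintf("WAVELENGTH=%.8f;\n", det$wavelength),
    sprintf("BEAM_CENTER_X=%.6f;\n", det$beam_center[2] * det$pixel_size),
    sprintf("BEAM_CENTER_Y=%.6f;\n", det$beam_center[1] * det$pixel_size),
    "}\n")
  if (nchar(hdr, type = "bytes") > 512) stop("SMV header overflow")
  hdr <- paste0(hdr, strrep(" ", 512 - nchar(hdr, type = "bytes")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  vals <- as.integer(round(t(frame)))      # fast axis first
  # writeBin has no unsigned 16-bit: encode manually
  writeBin(as.raw(rbind(vals %% 256L, vals %/% 256L)), con)
  path
}

read_smv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 512)
  hdr <- rawToChar(hdr_raw[hdr_raw != as.raw(0)])
  get <- function(key, default = NA_real_) {
    m <- regmatches(hdr, regexpr(paste0(key, "=([^;]*);"), hdr))
    if (length(m) == 0) return(default)
    as.numeric(sub(";", "", sub(paste0(key, "="), "", m)))
  }
  hb <- get("HEADER_BYTES", 512)
  size1 <- get("SIZE1"); size2 <- get("SIZE2")
  if (is.na(size1) || is.na(size2)) stop("unreadable SMV header: ", path)
  big <- grepl("BYTE_ORDER= *big_endian", hdr)
  seek(con, hb)
  vals <- readBin(con, "integer", n = size1 * size2, size = 2, signed = FALSE,
                  endian = if (big) "big" else "little")
  if (length(vals) < size1 * size2) stop("truncated SMV data block")
  frame <- t(matrix(vals, nrow = size1))   # fast axis = cols
  px <- get("PIXEL_SIZE"); dist <- get("DISTANCE"); wl <- get("WAVELENGTH")
  det <- NULL
  if (!is.na(px) && !is.na(dist)) {
    bc <- c(get("BEAM_CENTER_Y") / px, get("BEAM_CENTER_X") / px)
    if (anyNA(bc)) bc <- (dim(frame) + 1) / 2
    det <- detector_geometry(shape = dim(frame), pixel_size = px,
                             distance = dist,
                             wavelength = if (is.na(wl)) electron_wavelength() else wl,
                             beam_center = bc)
  }
  list(data = frame, detector = det)
}
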