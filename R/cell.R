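#' Real-space cell matrix from cell constants
#'
#' Builds the 3x3 matrix whose columns are the cell vectors a, b, c (in
#' Angstrom) in a right-handed Cartesian lab frame, using the standard
#' convention: a along +x, b in the xy plane, c completing the right-handed
#' set. The beam is taken along +z throughout the package.
#'
#' @param cell numeric length-6: a, b, c (Angstrom), alpha, beta, gamma (degrees).
#' @return 3x3 matrix, columns = a, b, c.
#' @export
cell_matrix <- function(cell) {
  stopifnot(length(cell) == 6, all(cell > 0))
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  ca <- cos(al); cb <- cos(be); cg <- cos(ga); sg <- sin(ga)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("cell constants do not define a valid cell")
  cx <- cc * cb
  cy <- cc * (ca - cb * cg) / sg
  cz <- cc * sqrt(v2) / sg
  cbind(c(a, 0, 0), c(b * cg, b * sg, 0), c(cx, cy, cz))
}

#' Cell constants from a cell-vector matrix
#'
#' @param M 3x3 matrix with columns a, b, c.
#' @return numeric length-6: lengths (Angstrom) and angles (degrees).
#' @export
cell_constants <- function(M) {
  len <- sqrt(colSums(M^2))
  ang <- c(angle_between(M[, 2], M[, 3]),
           angle_between(M[, 1], M[, 3]),
           angle_between(M[, 1], M[, 2]))
  c(len, ang)
}

#' Relativistic electron wavelength
#'
#' Standard relativistic de Broglie wavelength for an accelerating voltage,
#' `lambda = h / sqrt(2 m0 e V (1 + e V / (2 m0 c^2)))`.
#'
#' @param kv accelerating voltage in kilovolts (e.g. 200).
#' @return wavelength in Angstrom.
#' @export
electron_wavelength <- function(kv = 200) {
  stopifnot(kv > 0)
  V <- kv * 1e3
  12.2639 / sqrt(V * (1 + 0.97845e-6 * V))
}
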