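#' Rotation matrix from axis and angle
#'
#' Builds the proper rotation matrix describing a right-handed rotation by
#' `angle_deg` degrees about `axis` (Rodrigues' formula). The axis need not be
#' normalized.
#'
#' @param axis numeric length-3 vector; must have nonzero norm.
#' @param angle_deg rotation angle in degrees.
#' @return a 3x3 orthogonal matrix with determinant +1.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  stopifnot(length(axis) == 3, is.finite(angle_deg))
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) stop("rotation axis must have nonzero norm")
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Axis-angle decomposition of a rotation matrix
#'
#' Extracts the rotation angle (degrees, in \[0, 180\]) and unit axis of a
#' proper rotation. The angle comes from `atan2(|skew part|, trace - 1)`,
#' which is well conditioned over the whole range; near 180 degrees the axis
#' is recovered from the symmetric part `R + I`. The axis sign is
#' canonicalized so its first nonzero component is positive. For the identity
#' the axis is undefined and returned as `c(0, 0, 1)` by convention.
#'
#' @param R a 3x3 proper rotation matrix.
#' @return list with `axis` (unit 3-vector) and `angle` (degrees).
#' @export
axis_angle <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  skew <- (R - t(R)) / 2
  s <- c(skew[3, 2], skew[1, 3], skew[2, 1]) # sin(theta) * axis
  sn <- sqrt(sum(s^2))
  cs <- (sum(diag(R)) - 1) / 2
  angle <- atan2(sn, cs) * 180 / pi
  if (angle < 1e-9) {
    return(list(axis = c(0, 0, 1), angle = angle))
  }
  if (angle < 179) {
    axis <- s / sn
  } else {
    # near 180 deg the skew part vanishes; the axis is the null vector of
    # R - I, recovered at machine precision from its SVD
    sv <- svd(R - diag(3))
    axis <- sv$v[, 3]
    # fix sign consistency with the (tiny but usually nonzero) skew part
    if (sn > 1e-12 && sum(axis * s) < 0) axis <- -axis
  }
  axis <- canonical_axis_sign(axis)
  list(axis = axis, angle = angle)
}

canonical_axis_sign <- function(axis, tol = 1e-12) {
  for (k in 1:3) {
    if (abs(axis[k]) > tol) {
      if (axis[k] < 0) axis <- -axis
      break
    }
  }
  axis
}

#' Relative rotation between two orientation matrices
#'
#' Finds the proper rotation `R` best mapping the columns of `M0` onto the
#' columns of `Mi` in the least-squares (orthogonal Procrustes) sense, i.e.
#' minimizing `||R M0 - Mi||_F` with `det(R) = +1`, and returns its axis-angle
#' decomposition. With exactly rotated inputs (`Mi = R M0`) this coincides
#' with `Mi %*% solve(M0)`; with noisy, slightly non-orthogonal matrices the
#' Procrustes solution absorbs the non-rotational part.
#'
#' @param M0,Mi 3x3 matrices whose columns are the cell vectors a, b, c in the
#'   lab frame.
#' @return list with `axis` (unit 3-vector, canonical sign), `angle`
#'   (degrees in \[0, 180\]) and `R` (the 3x3 rotation).
#' @export
relative_rotation <- function(M0, Mi) {
  stopifnot(all(dim(M0) == c(3, 3)), all(dim(Mi) == c(3, 3)))
  H <- Mi %*% t(M0)
  sv <- svd(H)
  if (min(sv$d) < 1e-12 * max(sv$d)) stop("degenerate (rank-deficient) orientation matrix")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aa <- axis_angle(R)
  list(axis = aa$axis, angle = aa$angle, R = R)
}

#' Uniformly random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) (random unit quaternion method).
#' Uses the current RNG state.
#'
#' @return a 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quaternion_to_matrix(q)
}

# w, x, y, z convention
quaternion_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Angle between two vectors
#'
#' @param u,v numeric 3-vectors.
#' @return angle in degrees in \[0, 180\].
#' @export
angle_between <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  if (cu == 0 || cv == 0) stop("zero-length vector")
  # atan2 form is accurate for near-parallel vectors
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}
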