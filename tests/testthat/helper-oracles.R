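# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

# Shepperd-style quaternion extraction from a rotation matrix, then
# axis-angle via 2*atan2(|v|, |w|). Independent of the package's
# skew-part / R+I route.
oracle_axis_angle <- function(R) {
  tr <- sum(diag(R))
  qs <- c(1 + tr, 1 + 2 * R[1, 1] - tr, 1 + 2 * R[2, 2] - tr, 1 + 2 * R[3, 3] - tr)
  i <- which.max(qs)
  s <- 2 * sqrt(qs[i])
  q <- switch(i,
    c(s / 4,
      (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s),
    c((R[3, 2] - R[2, 3]) / s,
      s / 4, (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s),
    c((R[1, 3] - R[3, 1]) / s,
      (R[1, 2] + R[2, 1]) / s, s / 4, (R[2, 3] + R[3, 2]) / s),
    c((R[2, 1] - R[1, 2]) / s,
      (R[1, 3] + R[3, 1]) / s, (R[2, 3] + R[3, 2]) / s, s / 4))
  if (q[1] < 0) q <- -q
  vn <- sqrt(sum(q[2:4]^2))
  angle <- 2 * atan2(vn, q[1]) * 180 / pi
  axis <- if (vn < 1e-14) c(0, 0, 1) else q[2:4] / vn
  for (k in 1:3) {
    if (abs(axis[k]) > 1e-12) {
      if (axis[k] < 0) axis <- -axis
      break
    }
  }
  list(axis = axis, angle = angle)
}

# quaternion (w, x, y, z) product, for brute-force rotation composition
oracle_quat_mul <- function(p, q) {
  c(p[1] * q[1] - sum(p[2:4] * q[2:4]),
    p[1] * q[2:4] + q[1] * p[2:4] + c(p[3] * q[4] - p[4] * q[3],
                                      p[4] * q[2] - p[2] * q[4],
                                      p[2] * q[3] - p[3] * q[2]))
}

oracle_quat_from_axis_angle <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180 / 2
  c(cos(th), sin(th) * u)
}

# helper: build an IntensityTraces object directly from a value matrix
make_traces <- function(values, fluence_axis = seq_len(ncol(values)) * 0.01) {
  structure(list(values = values, fluence_axis = fluence_axis,
                 spot_id = seq_len(nrow(values)),
                 normalization_state = "raw",
                 clipped = rep(FALSE, nrow(values))),
            class = "IntensityTraces")
}

# helper: synthetic unimodal traces peaking at given frames
make_peaked_traces <- function(peak_frames, n_frames = 100, width2 = 50,
                               peak_sd = 1, seed = 1) {
  set.seed(seed)
  v <- t(sapply(peak_frames, function(p) {
    exp(-((seq_len(n_frames) - p - stats::rnorm(1, 0, peak_sd))^2) / width2)
  }))
  make_traces(v)
}

# helper: a small constant-value frame stack
const_stack <- function(value, shape = c(16, 16), n = 3, flux = 0.01) {
  frame_stack(array(value, c(shape, n)), flux = flux)
}
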