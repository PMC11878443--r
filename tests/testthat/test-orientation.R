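# shorthand builders for the disambiguation / rejection / net-rotation chain
drift_track <- function(model, n = 100, rate = 1, fpf = 0.01, axis = c(0, 0, 1),
                        jitter = 0) {
  simulate_orientation_track(
    model, bir_trajectory(n_frames = n, fluence_per_frame = fpf,
                          drift_rate = rate, drift_axis = axis,
                          jitter_sd = jitter))
}

# TRUE when out equals truth times one single global operator
matches_modulo_global_op <- function(out, truth, ops, tol = 1e-9) {
  n <- dim(out$matrices)[3]
  for (S in ops) {
    if (max(abs(out$matrices - array(apply(truth$matrices, 3, function(M) M %*% S),
                                     c(3, 3, n)))) < tol) {
      return(TRUE)
    }
  }
  FALSE
}

test_that("disambiguation recovers noise-free scrambled tracks modulo a global op", {
  for (pg in c("2", "222", "4", "422")) {
    m <- crystal_model(cell = if (pg %in% c("4", "422")) c(8, 8, 12, 90, 90, 90)
                       else c(10.2, 14.8, 6.9, 90, 90, 90),
                       point_group = pg, seed = 5)
    s <- drift_track(m)
    sc <- scramble_indexing(s, m, seed = 21)
    out <- disambiguate(sc)
    expect_true(matches_modulo_global_op(out, s, point_group_rotations(pg)),
                label = paste("point group", pg))
  }
})

test_that("disambiguation with the identity group is a no-op", {
  m <- crystal_model(point_group = "1")
  s <- drift_track(m, n = 20)
  out <- disambiguate(s, ops = point_group_rotations("1"))
  expect_equal(out$matrices, s$matrices)
})

test_that("equidistant candidates resolve to the lowest operator index", {
  # construct a degenerate case: previous frame orthogonal cell, candidate
  # frames relate by a 2-fold; distances tie exactly for a matrix whose
  # scrambled settings are reflections of each other
  m <- crystal_model(cell = c(10, 10, 10, 90, 90, 90), point_group = "222")
  ops <- point_group_rotations("222")
  M0 <- cell_matrix(m$cell)
  # a 90-deg rotation about z makes M*op2 and M*op3 equidistant from M0 for
  # this symmetric cell
  M <- rotation_about_axis(c(0, 0, 1), 90) %*% M0
  d <- sapply(ops, function(S) sum((M %*% S - M0)^2))
  ties <- which(abs(d - min(d)) < 1e-9)
  expect_gt(length(ties), 1) # the construction is genuinely degenerate
  ser <- orientation_series(array(c(M0, M), c(3, 3, 2)), c(0.01, 0.02),
                            m$cell, "222")
  out <- disambiguate(ser)
  expect_equal(out$matrices[, , 2], M %*% ops[[min(ties)]], tolerance = 1e-12)
})

test_that("disambiguation is idempotent and equivariant under a global op", {
  m <- crystal_model(seed = 9)
  s <- drift_track(m, n = 40)
  sc <- scramble_indexing(s, m, seed = 2)
  once <- disambiguate(sc)
  twice <- disambiguate(once)
  expect_equal(twice$matrices, once$matrices, tolerance = 1e-12)
  ops <- point_group_rotations(m$point_group)
  S <- ops[[3]]
  pre <- sc
  for (i in seq_len(length(pre))) pre$matrices[, , i] <- pre$matrices[, , i] %*% S
  out_pre <- disambiguate(pre)
  n <- length(s)
  expect_equal(out_pre$matrices,
               array(apply(once$matrices, 3, function(M) M %*% S), c(3, 3, n)),
               tolerance = 1e-12)
})

test_that("constant series yields no mis-index flags", {
  m <- crystal_model()
  s <- drift_track(m, n = 20, rate = 0)
  out <- reject_misindexed(s)
  expect_length(attr(out, "rejected"), 0)
  expect_true(all(out$valid))
})

test_that("a single shifted frame is flagged, and only that frame", {
  m <- crystal_model(seed = 4)
  s <- drift_track(m, n = 50, rate = 0.5, jitter = 0.02, axis = c(1, 1, 1) / sqrt(3))
  comp <- t(array(s$matrices, c(9, 50)))
  shifted <- s
  # shift frame 5's a_x by 10 sigma of the perturbed population, computed by hand
  for (iter in 1:3) { # fixed point of sigma under the injected shift
    sig <- stats::sd(t(array(shifted$matrices, c(9, 50)))[, 1])
    shifted$matrices[1, 1, 5] <- s$matrices[1, 1, 5] + 10 * sig
  }
  sig_hand <- stats::sd(t(array(shifted$matrices, c(9, 50)))[, 1])
  expect_gt(abs(shifted$matrices[1, 1, 5] - shifted$matrices[1, 1, 4]), 2 * sig_hand)
  out <- reject_misindexed(shifted)
  expect_equal(attr(out, "rejected"), 5L)
  expect_false(out$valid[5])
  expect_equal(sum(!out$valid), 1)
})

test_that("smooth drift with small steps is never flagged", {
  m <- crystal_model(seed = 6)
  # per-step change is ~1/100 of the component range, hence far below 2 sigma
  s <- drift_track(m, n = 100, rate = 2)
  out <- reject_misindexed(s)
  expect_length(attr(out, "rejected"), 0)
})

test_that("short series skip rejection with a warning", {
  m <- crystal_model()
  s <- drift_track(m, n = 2)
  expect_warning(out <- reject_misindexed(s), "fewer than 3")
  expect_true(all(out$valid))
})

test_that("net rotation of a pure drift track matches the generator", {
  m <- crystal_model(seed = 2)
  s <- drift_track(m, n = 150, rate = 1, fpf = 0.01, axis = c(0, 1, 0))
  nr <- net_rotation(s)
  expect_equal(nr$final_angle, 1.49, tolerance = 1e-9)
  expect_lt(angle_between(nr$final_axis, c(0, 1, 0)), 0.1)
  expect_equal(nr$per_frame_angle, (0:149) * 0.01, tolerance = 1e-9)
})

test_that("rotation about c leaves c fixed and moves a and b by the full angle", {
  m <- crystal_model(cell = c(10, 12, 8, 90, 90, 90))
  s <- drift_track(m, n = 50, rate = 2, axis = c(0, 0, 1))
  nr <- net_rotation(s)
  expect_equal(nr$per_vector_angles[, 3], rep(0, 50), tolerance = 1e-7)
  expect_equal(nr$per_vector_angles[, 1], nr$per_frame_angle, tolerance = 1e-7)
  expect_equal(nr$per_vector_angles[, 2], nr$per_frame_angle, tolerance = 1e-7)
})

test_that("static series has identically zero rotation summary", {
  m <- crystal_model()
  s <- drift_track(m, n = 10, rate = 0)
  nr <- net_rotation(s)
  expect_equal(max(nr$per_frame_angle), 0, tolerance = 1e-9)
  expect_equal(max(abs(nr$per_vector_angles)), 0, tolerance = 1e-6)
})

test_that("per-vector angles never exceed the net rotation angle", {
  m <- crystal_model(seed = 13)
  s <- drift_track(m, n = 60, rate = 3, axis = c(2, -1, 1) / sqrt(6), jitter = 0.1)
  nr <- net_rotation(s)
  for (v in 1:3) {
    expect_true(all(nr$per_vector_angles[, v] <= nr$per_frame_angle + 1e-6))
  }
})

test_that("net rotation respects a fluence cap and needs two valid frames", {
  m <- crystal_model()
  s <- drift_track(m, n = 100, rate = 1, fpf = 0.01)
  nr <- net_rotation(s, max_fluence = 0.5)
  expect_equal(nr$final_fluence, 0.5, tolerance = 1e-12)
  expect_equal(nr$final_angle, 0.49, tolerance = 1e-9)
  s$valid[2:100] <- FALSE
  expect_error(net_rotation(s), "2 valid")
})

test_that("quakes are detected at the right fluence; drift alone is not a quake", {
  m <- crystal_model(seed = 3)
  q <- simulate_orientation_track(
    m, bir_trajectory(n_frames = 100, fluence_per_frame = 0.01,
                      quake_fluence = 0.08, quake_angle = 3,
                      quake_axis = c(1, 0, 0)))
  nr <- net_rotation(q)
  qf <- detect_quake(nr, threshold = 1)
  expect_false(is.null(qf))
  expect_lte(abs(qf - 0.08), 0.011) # within one frame
  d <- drift_track(m, n = 100, rate = 1)
  expect_null(detect_quake(net_rotation(d), threshold = 1))
})

# exact observed spots: the noise-free predicted positions for orientation M
exact_spots <- function(m, M, det) {
  pred <- predict_spots(m, M, det)
  spot_table(cbind(pred$row, pred$col), mask_radius = 25)
}

test_that("refinement is a fixed point at the true orientation", {
  m <- crystal_model(seed = 2)
  det <- detector_geometry()
  set.seed(3)
  M <- random_rotation() %*% cell_matrix(m$cell)
  sp <- exact_spots(m, M, det)
  expect_gte(nrow(sp), 10)
  out <- refine_orientation(sp, M, m, det)
  expect_true(attr(out, "refined"))
  expect_lt(relative_rotation(M, out)$angle, 1e-6)
})

test_that("a slightly wrong candidate is refined back to the truth", {
  m <- crystal_model(seed = 2)
  det <- detector_geometry()
  set.seed(3)
  M <- random_rotation() %*% cell_matrix(m$cell)
  sp <- exact_spots(m, M, det)
  cand <- rotation_about_axis(c(0, 0, 1), 0.5) %*% M
  out <- refine_orientation(sp, cand, m, det)
  expect_true(attr(out, "refined"))
  expect_lt(relative_rotation(M, out)$angle, 0.01)
})

test_that("refinement of detected (pixel-rounded) spots does not diverge", {
  m <- crystal_model(seed = 2)
  det <- detector_geometry()
  set.seed(3)
  M <- random_rotation() %*% cell_matrix(m$cell)
  img <- render_diffraction_frame(m, M, 0, det, poisson = FALSE, background = 0)
  st <- frame_stack(array(img, c(dim(img), 1)), detector = det,
                    check_counts = FALSE)
  sp <- find_spots(detection_image(st), 1.5, background = 0.5, geometry = det,
                   min_area = 3)
  cand <- rotation_about_axis(c(0, 0, 1), 0.5) %*% M
  out <- refine_orientation(sp, cand, m, det)
  expect_true(attr(out, "refined"))
  # in-plane error is corrected; pixel rounding leaves a small tilt residual
  expect_lt(relative_rotation(M, out)$angle, 0.4)
})

test_that("a grossly wrong candidate is refused", {
  m <- crystal_model(seed = 2)
  det <- detector_geometry()
  set.seed(3)
  M <- random_rotation() %*% cell_matrix(m$cell)
  img <- render_diffraction_frame(m, M, 0, det, poisson = FALSE, background = 0)
  st <- frame_stack(array(img, c(dim(img), 1)), detector = det,
                    check_counts = FALSE)
  sp <- find_spots(detection_image(st), 1.5, background = 0.5, geometry = det,
                   min_area = 3)
  cand <- rotation_about_axis(c(1, 0, 0), 30) %*% M
  expect_warning(out <- refine_orientation(sp, cand, m, det, capture_radius = 3),
                 "refused")
  expect_false(attr(out, "refined"))
  expect_equal(unclass(out)[1:3, 1:3], cand, ignore_attr = TRUE)
})

test_that("orientation tables round-trip through TSV", {
  m <- crystal_model(seed = 8)
  s <- drift_track(m, n = 12, rate = 1, jitter = 0.05)
  s$valid[4] <- FALSE
  path <- tempfile(fileext = ".tsv")
  write_orientation_table(s, path)
  r <- read_orientation_table(path, cell = m$cell, point_group = m$point_group)
  expect_equal(r$matrices, s$matrices, tolerance = 1e-12)
  expect_equal(r$fluence_axis, s$fluence_axis, tolerance = 1e-12)
  expect_equal(r$valid, s$valid)
})
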