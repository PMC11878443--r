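# direct injection of Gaussian spots into otherwise clean frames
inject_spot <- function(img, row, col, intensity, sigma = 1.5) {
  w <- ceiling(4 * sigma)
  rr <- max(1, row - w):min(nrow(img), row + w)
  cc <- max(1, col - w):min(ncol(img), col + w)
  img[rr, cc] <- img[rr, cc] + intensity / (2 * pi * sigma^2) *
    outer(exp(-(rr - row)^2 / (2 * sigma^2)), exp(-(cc - col)^2 / (2 * sigma^2)))
  img
}

test_that("detection image of a single frame is its smoothed copy", {
  img <- inject_spot(matrix(2, 64, 64), 30, 40, 500)
  st <- frame_stack(array(img, c(64, 64, 1)))
  di <- detection_image(st)
  expect_equal(di, birtrack:::gaussian_blur(img, 1), tolerance = 1e-12)
})

test_that("max projection keeps spots appearing in any frame", {
  f1 <- inject_spot(matrix(2, 64, 64), 15, 15, 500)
  f2 <- inject_spot(matrix(2, 64, 64), 50, 50, 500)
  st <- frame_stack(array(c(f1, f2), c(64, 64, 2)))
  di <- detection_image(st)
  sp <- find_spots(di, 1.5, background = 2, min_area = 3)
  expect_equal(nrow(sp), 2)
  got <- sp[order(sp$row), ]
  expect_lt(max(abs(got$row - c(15, 50))), 1.5)
  expect_lt(max(abs(got$col - c(15, 50))), 1.5)
  # locality: around frame-2's spot the projection equals frame 2's smoothed copy
  sm2 <- birtrack:::gaussian_blur(f2, 1)
  expect_equal(di[45:55, 45:55], sm2[45:55, 45:55], tolerance = 1e-12)
})

test_that("find_spots on empty or all-zero images returns an empty table", {
  expect_equal(nrow(find_spots(matrix(0, 32, 32), 1.25)), 0)
  expect_equal(nrow(find_spots(matrix(5, 32, 32), 1.25, background = 5)), 0)
})

test_that("a single injected spot is found at the injected center", {
  img <- inject_spot(matrix(10, 100, 100), 42, 61, 50 * 2 * pi * 1.5^2)
  sp <- find_spots(img, 1.25, background = 10, min_area = 3)
  expect_equal(nrow(sp), 1)
  expect_lte(abs(sp$row - 42), 1)
  expect_lte(abs(sp$col - 61), 1)
})

test_that("spots closer than the mask radius merge; distant ones do not", {
  img <- matrix(1, 200, 200)
  img <- inject_spot(img, 50, 50, 2000)
  img <- inject_spot(img, 50, 150, 2000) # 100 px apart
  sp <- find_spots(img, 2, background = 1, min_area = 3)
  expect_equal(nrow(sp), 2)
  img2 <- matrix(1, 200, 200)
  img2 <- inject_spot(img2, 100, 95, 2000)
  img2 <- inject_spot(img2, 100, 105, 2000) # 10 px apart < 25
  sp2 <- find_spots(img2, 2, background = 1, min_area = 3)
  expect_equal(nrow(sp2), 1)
  expect_lte(abs(sp2$row - 100), 1)
  expect_lte(abs(sp2$col - 100), 1)
})

test_that("detection is invariant to a constant offset with matched background", {
  img <- inject_spot(matrix(0, 80, 80), 33, 47, 900)
  sp1 <- find_spots(img + 4, 1.5, background = 4, min_area = 3)
  sp2 <- find_spots(img + 10, 1.5, background = 10, min_area = 3)
  # threshold levels chosen so the same pixels pass: 1.5*4 - 4 = 2 = (1.5*10-10)/2.5
  sp1b <- find_spots(img + 4, 1.5, background = 4)
  expect_equal(sp1$row, sp2$row)
  expect_equal(sp1$col, sp2$col)
  expect_equal(sp1$row, sp1b$row)
})

test_that("diamond masks integrate the exact lattice-point count", {
  # oracle: enumerate |dr| + |dc| <= r over a grid
  r <- 25
  cnt <- sum(abs(outer(-30:30, rep(1, 61))) + abs(outer(rep(1, 61), -30:30)) <= r)
  expect_equal(cnt, 2 * r^2 + 2 * r + 1) # 1301
  st <- frame_stack(array(1, c(120, 120, 3)))
  sp <- spot_table(cbind(60, 60), mask_radius = 25)
  tr <- integrate_traces(st, sp)
  expect_equal(as.numeric(tr$values), rep(cnt, 3))
  expect_false(any(tr$clipped))
})

test_that("edge-clipped masks are flagged and summed over the clipped region", {
  st <- frame_stack(array(1, c(50, 50, 1)))
  sp <- spot_table(cbind(3, 25), mask_radius = 10)
  tr <- integrate_traces(st, sp)
  expect_true(tr$clipped[1])
  full <- 2 * 10^2 + 2 * 10 + 1
  expect_lt(tr$values[1, 1], full)
  expect_gt(tr$values[1, 1], 0)
})

test_that("empty frames integrate to zero and integration is linear", {
  z <- frame_stack(array(0, c(60, 60, 2)))
  sp <- spot_table(rbind(c(20, 20), c(40, 40)), mask_radius = 5)
  expect_true(all(integrate_traces(z, sp)$values == 0))
  set.seed(4)
  a <- array(rpois(60 * 60 * 2, 5), c(60, 60, 2))
  b <- array(rpois(60 * 60 * 2, 9), c(60, 60, 2))
  ta <- integrate_traces(frame_stack(a), sp)$values
  tb <- integrate_traces(frame_stack(b), sp)$values
  tab <- integrate_traces(frame_stack(a + b), sp)$values
  expect_equal(tab, ta + tb, tolerance = 1e-12)
})

test_that("overlapping diamonds assign shared pixels to the nearer center", {
  st <- frame_stack(array(1, c(60, 60, 1)))
  sp <- spot_table(rbind(c(30, 20), c(30, 28)), mask_radius = 10)
  tr <- integrate_traces(st, sp)
  # every pixel counted once: total equals union area
  off <- birtrack:::diamond_offsets(10)
  pix <- rbind(cbind(30 + off$dr, 20 + off$dc), cbind(30 + off$dr, 28 + off$dc))
  expect_equal(sum(tr$values[, 1]), nrow(unique(pix)))
  expect_gt(tr$values[1, 1], 0)
  expect_gt(tr$values[2, 1], 0)
})

test_that("summed_trace selects the brightest fraction and normalizes to 1", {
  set.seed(6)
  v <- matrix(runif(10 * 20, 0, 1), 10, 20)
  v[3, 7] <- 50
  v[8, 15] <- 40 # two dominant traces
  tr <- make_traces(v)
  s <- summed_trace(tr, top_fraction = 0.2)
  expect_setequal(attr(s, "selected"), c(3, 8))
  # brute-force oracle: sort per-trace maxima
  expect_setequal(attr(s, "selected"),
                  order(apply(v, 1, max), decreasing = TRUE)[1:2])
  expect_equal(max(s), 1)
  expect_equal(as.numeric(s), colSums(v[c(3, 8), ]) / max(colSums(v[c(3, 8), ])),
               tolerance = 1e-12)
})

test_that("summed_trace degenerate cases", {
  v <- matrix(rep(c(1, 2, 3, 2, 1), each = 4), 4, 5)
  s <- summed_trace(make_traces(v), top_fraction = 1)
  expect_equal(as.numeric(s), c(1, 2, 3, 2, 1) / 3, tolerance = 1e-12)
  s2 <- summed_trace(make_traces(v), top_fraction = 0.25)
  expect_equal(as.numeric(s2), c(1, 2, 3, 2, 1) / 3, tolerance = 1e-12)
  expect_error(summed_trace(make_traces(matrix(0, 2, 3))), "zero")
})

test_that("derivative profile of a constant trace is zero with zero bin SDs", {
  p <- derivative_profile(rep(1, 30), (1:30) * 0.02, bin_width = 0.1)
  expect_true(all(p$derivative == 0))
  expect_true(all(p$bin_sd[p$bin_n > 1] == 0))
})

test_that("derivative of exp(-D) approximates -exp(-D)", {
  fl <- seq(0.001, 2, by = 0.001)
  p <- derivative_profile(exp(-fl), fl, bin_width = 0.25)
  expect_equal(p$derivative, -exp(-p$mid_fluence), tolerance = 1e-4)
})

test_that("cumulative sum of the derivative reconstructs the trace to 1e-10", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    tr <- cumsum(rnorm(n)) / 10 + 2
    tr <- tr / max(tr)
    fl <- cumsum(runif(n, 0.005, 0.02))
    p <- derivative_profile(tr, fl)
    rec <- c(0, cumsum(p$derivative * p$dfluence))
    expect_lt(max(abs(rec - (tr - tr[1]))), 1e-10)
  }
  expect_error(derivative_profile(1, 0.1), "2 frames")
})

test_that("fluctuation summary aggregates per-bin SDs across crystals", {
  fl <- (1:40) * 0.05
  p1 <- derivative_profile(exp(-fl), fl, bin_width = 0.5)
  one <- fluctuation_summary(list(p1))
  expect_equal(one$mean_sd, p1$bin_sd)
  expect_true(all(one$sd_sd == 0))
  p2 <- derivative_profile(exp(-1.5 * fl), fl, bin_width = 0.5)
  two <- fluctuation_summary(list(p1, p2))
  expect_equal(two$mean_sd, (p1$bin_sd + p2$bin_sd) / 2)
  p3 <- derivative_profile(exp(-fl), fl, bin_width = 0.3)
  expect_error(fluctuation_summary(list(p1, p3)), "mismatched")
})

test_that("log-linear trace fits recover the generator decay rate within 5%", {
  m <- crystal_model(seed = 2)
  det <- detector_geometry()
  M <- rotation_about_axis(c(1, 1, 1), 15) %*% cell_matrix(m$cell)
  n <- 100
  ser <- orientation_series(array(rep(M, n), c(3, 3, n)), (1:n) * 0.02,
                            m$cell, m$point_group)
  stack <- render_dose_series(m, ser, det, background = 1)
  pred <- predict_spots(m, M, det)
  dmat <- as.matrix(stats::dist(cbind(pred$row, pred$col)))
  diag(dmat) <- Inf
  pred <- pred[apply(dmat, 1, min) >= 25 &
                 pred$base_intensity * pred$rocking > 500, ]
  expect_gte(nrow(pred), 20)
  di <- detection_image(stack)
  sp <- find_spots(di, 1.25, geometry = det)
  tr <- integrate_traces(stack, sp)
  fl <- stack$fluence_axis - stack$fluence_axis[1] # dose before each frame
  alphas <- vapply(seq_len(nrow(pred)), function(i) {
    j <- which.min((sp$row - pred$row[i])^2 + (sp$col - pred$col[i])^2)
    y <- tr$values[j, ] - tr$n_pixels[j] # background expectation is 1/px
    ok <- y > 50
    if (sum(ok) < 10) return(NA_real_)
    -unname(stats::coef(stats::lm(log(y[ok]) ~ I(fl[ok] / pred$d[i]^2)))[2])
  }, 0)
  expect_gte(sum(!is.na(alphas)), 20)
  expect_equal(stats::median(alphas, na.rm = TRUE), m$decay_rate, tolerance = 0.05)
})
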