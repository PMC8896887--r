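circle_frames <- function(n_frames, R, n_pts = 400, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n_pts + 1)[-1]
  lapply(seq_len(n_frames), function(i)
    cbind(center[1] + R * cos(th), center[2] + R * sin(th)))
}

test_that("polar resampling reproduces circles and ellipses", {
  st <- contour_to_polar(circle_frames(3, 10), M = 180)
  expect_equal(dim(st$rho), c(180L, 3L))
  expect_true(all(abs(st$rho - 10) < 0.01))
  # ellipse closed form rho(theta) = ab / sqrt((b cos)^2 + (a sin)^2)
  a <- 12; b <- 8
  th <- seq(0, 2 * pi, length.out = 721)[-1]
  fr <- list(cbind(a * cos(th), b * sin(th)))
  st2 <- contour_to_polar(fr, M = 90)
  truth <- a * b / sqrt((b * cos(st2$theta))^2 + (a * sin(st2$theta))^2)
  expect_true(all(abs(st2$rho[, 1] / truth - 1) < 0.005))
  # refinement consistency: doubling M leaves the frame mean unchanged
  st3 <- contour_to_polar(fr, M = 180)
  expect_equal(mean(st3$rho), mean(st2$rho), tolerance = 1e-3)
})

test_that("detrending removes per-frame mean exactly, including growth", {
  frames <- c(circle_frames(1, 10), circle_frames(1, 11), circle_frames(1, 12))
  st <- contour_to_polar(frames, M = 90)
  res <- detrend_frames(st)
  expect_equal(colMeans(res), rep(0, 3), tolerance = 1e-12)
  expect_true(all(abs(res) < 1e-6))   # pure size change leaves no residual
})

test_that("fluctuation amplitude matches the single-mode closed form", {
  # rho = R0 + a sin(3 theta) sin(w t) over full periods:
  # SD_t = |a sin(3 theta)|/sqrt(2), angular mean of |sin| = 2/pi
  R0 <- 10; amp <- 1
  n_frames <- 30
  tt <- (seq_len(n_frames) - 1) / n_frames * 2 * pi   # one full period
  th <- seq(0, 2 * pi, length.out = 1441)[-1]
  frames <- lapply(tt, function(t) {
    r <- R0 + amp * sin(3 * th) * sin(t)
    cbind(r * cos(th), r * sin(th))
  })
  st <- contour_to_polar(frames, M = 360)
  vt <- fluctuation_amplitude(detrend_frames(st))
  expect_equal(vt, amp * (2 / pi) / sqrt(2), tolerance = 0.02 * amp)
  # static contour gives exactly zero
  expect_equal(fluctuation_amplitude(detrend_frames(contour_to_polar(circle_frames(5, 8), M = 90))),
               0, tolerance = 1e-9)
  expect_error(fluctuation_amplitude(matrix(1, 10, 1)), "2 frames")
})

test_that("independent modes add in quadrature at the variance level", {
  mv <- make_membrane_movie(R0 = 10,
    modes = data.frame(k = c(2, 5), amplitude = c(0.8, 0.5), period = c(60, 150)),
    n_frames = 31, noise_sd = 0, seed = 7)
  m1 <- make_membrane_movie(R0 = 10, modes = data.frame(k = 2, amplitude = 0.8, period = 60),
                            n_frames = 31, noise_sd = 0, seed = 7)
  m2 <- make_membrane_movie(R0 = 10, modes = data.frame(k = 5, amplitude = 0.5, period = 150),
                            n_frames = 31, noise_sd = 0, seed = 7)
  vrms <- function(m) {
    st <- contour_to_polar(m$frames, M = 360)
    res <- detrend_frames(st)
    sqrt(mean(apply(res, 1, function(x) mean((x - mean(x))^2))))
  }
  expect_equal(vrms(mv)^2, vrms(m1)^2 + vrms(m2)^2, tolerance = 0.05 * vrms(mv)^2)
})

test_that("normalization by the reference group is stratum-wise and scale free", {
  v <- c(1, 2, 3, 4, 10, 20, 30, 40)
  ref <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  strat <- rep(c("a", "b"), each = 4)
  out <- normalize_fluctuations(v, ref, strat)
  expect_equal(out[1:4], c(1, 2, 3, 4) / 1.5)
  expect_equal(out[5:8], c(10, 20, 30, 40) / 15)
  expect_equal(normalize_fluctuations(3 * v, ref, strat), out)
  expect_equal(mean(out[ref & strat == "a"]), 1)
  expect_error(normalize_fluctuations(v, rep(FALSE, 8)), "empty reference")
})

test_that("mask shape index recovers the circle and square benchmarks", {
  n <- 400
  xs <- seq_len(n) - (n + 1) / 2
  disk <- outer(xs, xs, function(x, y) x^2 + y^2 <= 150^2)
  s <- shape_series_from_masks(list(disk), pixel_size = 0.5)
  expect_equal(s$shape_index, 2 * sqrt(pi), tolerance = 0.02 * 2 * sqrt(pi))
  expect_equal(round(s$shape_index, 2), 3.54, tolerance = 0.08)
  sq <- outer(xs, xs, function(x, y) abs(x) <= 120 & abs(y) <= 120)
  s2 <- shape_series_from_masks(list(sq), pixel_size = 1)
  expect_equal(s2$shape_index, 4, tolerance = 0.08)
  # pixel size cancels
  s3 <- shape_series_from_masks(list(sq), pixel_size = 7)
  expect_equal(s3$shape_index, s2$shape_index)
})

test_that("temporal CV is scale invariant and matches hand computation", {
  x <- c(3.6, 4.0, 4.4)
  expect_equal(cv_over_time(x), sqrt(mean((x - 4)^2)) / 4)
  expect_equal(cv_over_time(x), 0.0816, tolerance = 1e-3)
  expect_equal(cv_over_time(10 * x), cv_over_time(x))
  expect_equal(cv_over_time(rep(2, 10)), 0)
  expect_error(cv_over_time(c(-3, 1)), "positive")
})

test_that("breathing-ellipse generator round-trips mean and CV through masks", {
  ss <- make_shape_series(mean_s = 4.0, cv = 0.08, n_frames = 15,
                          resolution = 384, seed = 5)
  expect_equal(mean(ss$s_true), 4.0, tolerance = 1e-6)
  expect_equal(cv_over_time(ss$s_true), 0.08, tolerance = 1e-6)
  meas <- shape_series_from_masks(ss$masks, pixel_size = ss$pixel_size)
  expect_equal(mean(meas$shape_index), 4.0, tolerance = 0.02 * 4)
  expect_equal(cv_over_time(meas), 0.08, tolerance = 0.15 * 0.08)
  # cv = 0 gives constant masks
  ss0 <- make_shape_series(mean_s = 4.2, cv = 0, n_frames = 5,
                           resolution = 256, seed = 6)
  m0 <- shape_series_from_masks(ss0$masks, pixel_size = ss0$pixel_size)
  expect_lt(cv_over_time(m0), 0.01)
})

test_that("boundary intensity CoV detects half-bright boundaries and scaling", {
  n <- 200
  th <- seq(0, 2 * pi, length.out = 361)[-1]
  contour <- cbind(100 + 60 * cos(th), 100 + 60 * sin(th))
  img_u <- matrix(5, n, n)
  expect_equal(boundary_intensity_cov(contour, img_u), 0, tolerance = 1e-12)
  img_h <- outer(seq_len(n), seq_len(n), function(x, y) as.numeric(x > 100))
  cv <- boundary_intensity_cov(contour, img_h, band_width = 2)
  expect_equal(cv, 1.0, tolerance = 0.15)
  expect_equal(boundary_intensity_cov(contour, 10 * img_h, band_width = 2), cv,
               tolerance = 1e-10)
})

test_that("fluctuation differential epsilon matches the amplitude ratio", {
  expect_equal(epsilon_estimate(1, 1), 0)
  expect_equal(epsilon_estimate(1.39, 1.91), 1.91 / 1.39 - 1)
  expect_equal(epsilon_estimate(1.39, 1.91), 0.374, tolerance = 1e-3)
  expect_equal(epsilon_estimate(2 * 1.39, 2 * 1.91), epsilon_estimate(1.39, 1.91))
  expect_error(epsilon_estimate(0, 1), "> 0")
})
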