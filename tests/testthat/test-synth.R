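test_that("membrane movie generator is reproducible and star convex", {
  m1 <- make_membrane_movie(seed = 3)
  m2 <- make_membrane_movie(seed = 3)
  expect_identical(m1$frames, m2$frames)
  m3 <- make_membrane_movie(seed = 4)
  expect_false(identical(m1$frames[[1]], m3$frames[[1]]))
  expect_error(make_membrane_movie(R0 = 3, modes = data.frame(k = 2, amplitude = 2, period = 60),
                                   seed = 1), "star-convex")
  expect_error(make_membrane_movie(), "seed")
})

test_that("no modes and no noise give zero ground truth and zero measured V_T", {
  m <- make_membrane_movie(R0 = 8, modes = data.frame(k = integer(), amplitude = numeric(),
                                                      period = numeric()),
                           noise_sd = 0, seed = 2)
  expect_equal(m$ground_truth$vt_true, 0)
  st <- contour_to_polar(m$frames, M = 180)
  expect_lt(fluctuation_amplitude(detrend_frames(st)), 1e-9)
})

test_that("single-mode ground truth equals the closed form and is recovered", {
  # k=3, a=1, sampled over integer periods: V_T = a (2/pi)/sqrt(2) ~ 0.450 a
  m <- make_membrane_movie(R0 = 7.2, modes = data.frame(k = 3, amplitude = 1, period = 60),
                           n_frames = 31, frame_interval = 10, noise_sd = 0, seed = 5)
  # analytic per-mode SD over the 31 sampled frames enters the stored truth
  expect_equal(m$ground_truth$vt_true, 0.450, tolerance = 0.02)
  st <- contour_to_polar(m$frames, M = 360)
  vt <- fluctuation_amplitude(detrend_frames(st))
  expect_equal(vt, m$ground_truth$vt_true, tolerance = 0.02 * m$ground_truth$vt_true)
})

test_that("V_T recovery holds within 5% under pixel-scale noise", {
  m <- make_membrane_movie(R0 = 7.2,
    modes = data.frame(k = c(2, 3, 5), amplitude = c(0.6, 0.8, 0.3), period = c(60, 100, 150)),
    n_frames = 31, noise_sd = 0.01 * 7.2, seed = 8)
  st <- contour_to_polar(m$frames, M = 360)
  vt <- fluctuation_amplitude(detrend_frames(st))
  expect_equal(vt, m$ground_truth$vt_true, tolerance = 0.05 * m$ground_truth$vt_true)
})

test_that("aggregate generator arrangements are labeled as requested", {
  agg <- make_aggregate(20, "core_shell", seed = 12)
  d <- sqrt(rowSums(sweep(agg$positions, 2, colMeans(agg$positions))^2))
  expect_true(mean(d[agg$cell_type == "PrE"]) > mean(d[agg$cell_type == "EPI"]))
  expect_equal(sum(agg$cell_type == "PrE"), 10)
  # packing respects the minimum separation
  expect_gte(min(dist(agg$positions)), 1.9 - 1e-9)
  # determinism
  agg2 <- make_aggregate(20, "core_shell", seed = 12)
  expect_identical(agg$positions, agg2$positions)
})

test_that("doublet generator stores exact ground truth and adds angle noise", {
  d0 <- make_doublet(1, 1, 1.2, angle_noise_sd = 0, seed = 3)
  gt <- attr(d0, "ground_truth")
  expect_equal(d0$theta_1, gt$theta_1)
  d1 <- make_doublet(1, 1, 1.2, angle_noise_sd = 2, seed = 3)
  expect_false(d1$theta_1 == gt$theta_1)
  expect_equal(d1$theta_1, gt$theta_1, tolerance = 10)
})

test_that("doublet ensembles propagate angle noise consistently (delta method)", {
  # beta = cos(t1)/cos(t2); Var(beta) ~ (d beta/d t1)^2 s^2 + (d beta/d t2)^2 s^2
  g1 <- 1.15; g2 <- 1; g12 <- 1.3; sd_deg <- 1.5
  d0 <- make_doublet(g1, g2, g12, angle_noise_sd = 0, seed = 1)
  t1 <- d0$theta_1 * pi / 180; t2 <- d0$theta_2 * pi / 180
  s <- sd_deg * pi / 180
  # theta_1 is the mean of two noisy sides -> variance s^2/2, same for theta_2
  var_beta <- (sin(t1) / cos(t2))^2 * s^2 / 2 +
    (cos(t1) * sin(t2) / cos(t2)^2)^2 * s^2 / 2
  betas <- vapply(1:400, function(i) {
    d <- make_doublet(g1, g2, g12, angle_noise_sd = sd_deg, seed = 1000 + i)
    affinity_parameter(d$theta_1, d$theta_2)
  }, 0)
  expect_equal(sd(betas), sqrt(var_beta), tolerance = 0.2 * sqrt(var_beta))
})

test_that("AFM generator inverts the compression relation exactly when noise free", {
  T_star <- 10e-9 * 3 / (2 * pi * 1e-5)   # tension giving F = 10 nN at r_c = 5 um
  r <- make_afm_record(T_true = T_star, r_mid = 10e-6, h_cell = 2 * sqrt(75) * 1e-6,
                       seed = 2)
  # r_c = 5 um for this height: F should be 10 nN
  expect_equal(r$r_c, 5e-6, tolerance = 1e-9)
  expect_equal(r$F, 10e-9, tolerance = 1e-9)
  expect_equal(afm_tension(r$F, r$r_mid, r$r_c), r$ground_truth$T_true, tolerance = 1e-9)
  expect_equal(afm_tension(10e-9, 10e-6, 5e-6), T_star, tolerance = 1e-12)
})

test_that("tension estimate is unbiased under relative force noise", {
  Ts <- vapply(1:1000, function(i) {
    r <- make_afm_record(T_true = 5e-4, r_mid = 10e-6, h_cell = 9e-6,
                         noise_sd = 0.05, seed = i)
    afm_tension(r$F, r$r_mid, r$r_c)
  }, 0)
  expect_equal(mean(Ts), 5e-4, tolerance = 0.01)
})

test_that("vertex mixture generator balances subtypes deterministically", {
  mx <- make_vertex_mixture(33, seed = 4)
  expect_lte(abs(sum(mx$subtype == 1) - sum(mx$subtype == 2)), 1)
  expect_true(all(mx$centers >= 0 & mx$centers <= mx$box))
  mx2 <- make_vertex_mixture(33, seed = 4)
  expect_identical(mx, mx2)
  expect_equal(sort(unique(mx$p0)), c(3.65, 4.05))
})
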