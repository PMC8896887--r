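test_that("affinity parameter matches cosine ratio and reciprocity", {
  expect_equal(affinity_parameter(60, 60), 1.0)
  expect_equal(affinity_parameter(60, 50.72), cos(60 * pi / 180) / cos(50.72 * pi / 180))
  expect_equal(affinity_parameter(60, 50.72), 0.790, tolerance = 2e-3)
  expect_equal(affinity_parameter(40, 70) * affinity_parameter(70, 40), 1.0)
  expect_error(affinity_parameter(95, 40), "between 0 and 90")
  expect_error(affinity_parameter(0, 40), "between 0 and 90")
})

test_that("tension force balance gives symmetric and ordered contact angles", {
  d <- doublet_from_tensions(1, 1, 1.2)
  expect_equal(d$theta_1, d$theta_2)
  # higher tension on cell 1 -> smaller angle on cell 1
  d2 <- doublet_from_tensions(1.3, 1, 1.2)
  expect_lt(d2$theta_1, d2$theta_2)
  # balance equations hold
  g1 <- 1.3; g2 <- 1; g12 <- 1.2
  t1 <- d2$theta_1 * pi / 180; t2 <- d2$theta_2 * pi / 180
  expect_equal(g1 * cos(t1) + g2 * cos(t2), g12, tolerance = 1e-10)
  expect_equal(g1 * sin(t1), g2 * sin(t2), tolerance = 1e-10)
  expect_error(doublet_from_tensions(1, 1, 2.5), "no physical doublet")
})

test_that("contact angle measured from the rendered contour matches the solved angle", {
  for (g12 in c(0.8, 1.2, 1.6)) {
    d <- doublet_from_tensions(1, 1, g12)
    m <- external_contact_angle(doublet_contour(d))
    expect_equal(m$theta_1, d$theta_1, tolerance = 1)
    expect_equal(m$theta_2, d$theta_2, tolerance = 1)
    expect_equal(m$waist, d$waist, tolerance = 0.01 * d$waist)
  }
})

test_that("contact angle measurement is rotation invariant", {
  d <- doublet_from_tensions(1.2, 0.9, 1.3)
  ct <- doublet_contour(d)
  th <- runif(1, 0, 2 * pi)
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- list(cell1 = ct$cell1 %*% Rm, cell2 = ct$cell2 %*% Rm)
  m0 <- external_contact_angle(ct)
  m1 <- external_contact_angle(rot)
  expect_equal(m1$theta_1, m0$theta_1, tolerance = 0.2)
  expect_equal(m1$theta_2, m0$theta_2, tolerance = 0.2)
})

test_that("normalized contact size has the cap-geometry endpoints", {
  # nearly touching spheres: tiny waist
  d <- doublet_from_tensions(1, 1, 1.99)
  expect_lt(normalized_contact_size(d), 0.15)
  # strongly fused: waist approaches the mean diameter
  d2 <- doublet_from_tensions(1, 1, 0.05)
  expect_gt(normalized_contact_size(d2), 0.95)
  # analytic chord for equal caps: waist = 2 R sin(theta)
  d3 <- doublet_from_tensions(1, 1, 1.0, radius = 5)
  expect_equal(d3$waist, 2 * 5 * sin(d3$theta_1 * pi / 180), tolerance = 1e-10)
})

test_that("parallel-plate tension follows the compression force balance", {
  expect_equal(afm_tension(10e-9, 10e-6, 5e-6), 4.774648e-4, tolerance = 1e-6)
  # contact radius equal to mid radius is unphysical
  expect_error(afm_tension(1e-9, 5e-6, 5e-6), "smaller")
  # homogeneity in force
  expect_equal(afm_tension(3 * 2e-9, 8e-6, 4e-6), 3 * afm_tension(2e-9, 8e-6, 4e-6))
  # contact area geometry
  expect_equal(afm_contact_area(100, 0), 100)
  expect_equal(afm_contact_area(100, 10), 100 - pi / 4 * 100)
  expect_error(afm_contact_area(10, 10), "positive")
  # monotone decreasing in height
  h <- seq(0, 10, by = 2)
  expect_true(all(diff(vapply(h, function(x) afm_contact_area(100, x), 0)) < 0))
})

test_that("AFM batch recovers tension and the IQR filter flags outliers", {
  recs <- do.call(rbind, lapply(1:20, function(i) {
    r <- make_afm_record(T_true = 5e-4, r_mid = 10e-6, h_cell = 9e-6, seed = i)
    data.frame(F = r$F, r_mid = r$r_mid, A_mid = r$A_mid, h_cell = r$h_cell)
  }))
  out <- afm_tension_batch(recs)
  expect_equal(out$tension, rep(5e-4, 20), tolerance = 1e-9)
  recs$F[1] <- recs$F[1] * 25
  out2 <- afm_tension_batch(recs, iqr_filter = TRUE)
  expect_false(out2$kept[1])
  expect_true(all(out2$kept[-1]))
})
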