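test_that("SPV shape force equals the numeric Voronoi energy gradient", {
  cfg <- spv_config(n_cells = 24L, seed = 3)
  mx <- make_vertex_mixture(24, box = cfg$box, seed = 3)
  n <- 24L
  A0 <- rep(cfg$box^2 / n, n)
  P0 <- mx$p0 * sqrt(A0[1])
  E_of <- function(centers) {
    g <- voronoi_adjacency(centers, cfg$box)
    sum((g$area - A0)^2 + (g$perimeter - P0)^2)
  }
  still <- local({ c2 <- cfg; c2$v0 <- 0; c2$dt <- 1e-7; c2 })
  st <- spv_step(mx$centers, rep(0, n), still, mx$p0, 1, seed = 1)
  F_num <- (st$centers - mx$centers) / 1e-7
  for (i in c(2L, 11L)) for (d in 1:2) {
    h <- 1e-6
    cp <- mx$centers; cp[i, d] <- cp[i, d] + h
    cm <- mx$centers; cm[i, d] <- cm[i, d] - h
    fd <- -(E_of(cp) - E_of(cm)) / (2 * h)
    expect_equal(F_num[i, d], fd, tolerance = 1e-3 * max(1, abs(fd)))
  }
})

test_that("without propulsion the dynamics settle to a stationary minimum", {
  cfg <- spv_config(n_cells = 25L, v0 = 0, seed = 2)
  mx <- make_vertex_mixture(25, p0_pair = c(3.8, 3.8), box = cfg$box, seed = 2)
  st <- spv_step(mx$centers, rep(0, 25L), cfg, mx$p0, n_steps = 4000L, seed = 2)
  st2 <- spv_step(st$centers, st$polarity, cfg, mx$p0, n_steps = 100L, seed = 3)
  drift <- sqrt(max(rowSums((st2$centers - st$centers)^2)))
  expect_lt(drift, 1e-3 * cfg$box)
})

test_that("free-particle mean square displacement matches 2 (v0^2/Dr) t", {
  cfg <- spv_config(n_cells = 400L, v0 = 0.1, Dr = 1.0, dt = 0.01, seed = 5)
  set.seed(5)
  cen0 <- cbind(runif(400, 0, cfg$box), runif(400, 0, cfg$box))
  pol <- runif(400, 0, 2 * pi)
  tmax <- 40
  st <- spv_step(cen0, pol, cfg, rep(3.8, 400), n_steps = as.integer(tmax / cfg$dt),
                 seed = 6, shape_forces = FALSE, wrap = FALSE)
  msd <- mean(rowSums((st$centers - cen0)^2))
  expect_equal(msd, 2 * cfg$v0^2 / cfg$Dr * tmax, tolerance = 0.10)
})

test_that("centers remain inside the periodic box under full dynamics", {
  cfg <- spv_config(n_cells = 32L, duration = 20, seed = 9)
  mx <- make_vertex_mixture(32, box = cfg$box, seed = 9)
  st <- spv_step(mx$centers, runif(32, 0, 2 * pi), cfg, mx$p0,
                 n_steps = 2000L, seed = 10)
  expect_true(all(st$centers >= 0 & st$centers < cfg$box))
})

test_that("random initial labelings start unmixed by the demixing score", {
  # DP clips at zero, so the unclipped neighbour enrichment is centred on 0
  set.seed(7)
  enrich <- vapply(1:50, function(sd) {
    mx <- make_vertex_mixture(48, seed = sd)
    adj <- voronoi_adjacency(mx$centers, mx$box)
    dp <- demixing_parameter(adj$neighbors, mx$subtype)
    attr(dp, "f_same") - attr(dp, "f_rand")
  }, 0)
  expect_lt(abs(mean(enrich)), 3 * sd(enrich) / sqrt(50))
})

test_that("demixing runs are reproducible given the seed", {
  cfg <- spv_config(n_cells = 32L, duration = 5, seed = 21)
  r1 <- run_demixing(cfg, n_records = 4L)
  r2 <- run_demixing(cfg, n_records = 4L)
  expect_identical(r1$dp, r2$dp)
  expect_identical(r1$centers, r2$centers)
})
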