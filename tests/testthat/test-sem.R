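test_that("Morse force has its minimum, asymptotics and derivative form", {
  expect_equal(morse_pair_force(1, 1, 1, 1), 0)
  expect_lt(abs(morse_pair_force(50, 1, 1, 1)), 1e-15)
  # attraction decays monotonically beyond the force extremum at re + ln(2)/a
  r <- seq(1 + log(2) + 0.05, 5, by = 0.2)
  f <- morse_pair_force(r, 1, 1, 1)
  expect_true(all(f < 0))
  expect_true(all(diff(f) > 0))
  # equals -dU/dr by central differences
  U <- function(r, D = 1, a = 1, re = 1) D * (exp(-2*a*(r-re)) - 2*exp(-a*(r-re)))
  h <- 1e-6
  expect_equal(morse_pair_force(0.5, 1, 1, 1), -(U(0.5+h) - U(0.5-h)) / (2*h),
               tolerance = 1e-6)
  expect_error(morse_pair_force(0, 1, 1, 1), "positive")
})

test_that("tension modulation is periodic with period tau/10", {
  expect_equal(tension_modulation(0.3, 5, 1.1, 0), 1)
  t <- runif(5, 0, 10)
  expect_equal(tension_modulation(t, 7, 0.4, 0.3),
               tension_modulation(t + 0.7, 7, 0.4, 0.3))
  # quarter of the fluctuation period after phase zero: sin = 1
  expect_equal(tension_modulation(5 / 40, 5, 0, 0.5), 1.5)
  expect_error(tension_modulation(1, 0, 0, 0.1), "> 0")
})

test_that("cortex identification flags single elements, hull vertices and no deep bulk", {
  expect_true(identify_cortex_elements(matrix(c(0, 0, 0), 1)))
  tet <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1))
  expect_true(all(identify_cortex_elements(tet)))
  set.seed(2)
  q <- runif_ball(200)
  fl <- identify_cortex_elements(q)
  hull <- fluctsort:::cpp_delaunay3(q)$hull
  expect_true(all(fl[hull]))
  r <- sqrt(rowSums(q^2))
  expect_gt(min(r[fl]), 0.5 * max(r))
})

test_that("cortex network equals the brute-force Delaunay edge set", {
  tet <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1))
  e <- build_cortex_network(tet)
  expect_equal(nrow(e), 6L)
  expect_true(all(e[, 1] < e[, 2]))   # no self loops, one direction per pair
  set.seed(7)
  p <- matrix(rnorm(60), 20)
  expect_identical(sorted_edges(build_cortex_network(p)), brute_delaunay_edges(p))
  # near-spherical shell, like a cortex
  set.seed(8)
  u <- matrix(rnorm(90), 30)
  u <- u / sqrt(rowSums(u^2)) * runif(30, 0.9, 1)
  expect_identical(sorted_edges(build_cortex_network(u)), brute_delaunay_edges(u))
})

test_that("coplanar cortex falls back to a planar triangulation with a warning", {
  set.seed(3)
  flat <- cbind(matrix(runif(24), 12), 0)
  expect_warning(e <- build_cortex_network(flat), "planar")
  expect_true(attr(e, "planar"))
  expect_gt(nrow(e), 11)
})

test_that("pairwise forces conserve momentum and vanish on an equilibrated cell", {
  cfg <- sim_config(n_start = 2L, n_end = 2L, seed = 5, delta_epi = 0.7,
                    epsilon = 0.4)
  st <- init_state(cfg)
  st$cell_type <- c("EPI", "PrE")
  F0 <- compute_forces(st, time = 1.23)
  expect_lt(max(abs(colSums(F0))), 1e-9)   # Newton's third law, fluctuations on
  st <- relax_state(st, duration = 3)
  F1 <- compute_forces(st, config = local({ q <- cfg; q$delta_epi <- 0; q }))
  expect_lt(max(abs(colSums(F1))), 1e-9)
  # relaxed single cells carry only small residual forces
  expect_lt(max(sqrt(rowSums(F1^2))), 2)
})

test_that("overdamped step obeys the closed form and guards the timestep", {
  cfg <- sim_config(n_start = 1L, n_end = 1L, seed = 2)
  st <- init_state(cfg)
  # zero force leaves positions unchanged
  st2 <- step_overdamped(st, matrix(0, nrow(st$positions), 3))
  expect_identical(st2$positions, st$positions)
  expect_equal(st2$time, st$time + cfg$dt)
  # constant force: displacement dt * F / drag per step
  Fm <- matrix(0, nrow(st$positions), 3)
  Fm[1, ] <- c(10, 0, 0)
  st3 <- step_overdamped(st, Fm, dt = 0.01, drag = 2)
  expect_equal(st3$positions[1, 1] - st$positions[1, 1], 0.01 * 10 / 2)
  # over-large displacement errors out
  Fbig <- matrix(0, nrow(st$positions), 3)
  Fbig[2, ] <- c(1e4, 0, 0)
  expect_error(step_overdamped(st, Fbig), "timestep too large")
})

test_that("halving dt converges the relaxation trajectory", {
  base <- sim_config(n_start = 2L, n_end = 2L, seed = 9, delta_epi = 0)
  run_with_dt <- function(dt, total = 0.4) {
    cfg <- base
    cfg$dt <- dt
    st <- init_state(cfg)
    st$cell_type <- c("EPI", "EPI")
    eff <- fluctsort:::effective_config(cfg)
    r <- fluctsort:::cpp_sem_advance(st$positions, st$cell_id,
                                     fluctsort:::unique_types(st), st$phase,
                                     eff, 0, as.integer(round(total / dt)), 1000000L)
    r$positions
  }
  p1 <- run_with_dt(0.001)
  p2 <- run_with_dt(0.0005)
  rms <- sqrt(mean((p1 - p2)^2))
  scale <- sqrt(mean(p1^2))
  expect_lt(rms / scale, 0.01)
})

test_that("growth doubles elements over a cycle and divisions conserve them", {
  cfg <- sim_config(n_start = 2L, n_end = 4L, seed = 4, n_elements_per_cell = 16L)
  st <- init_state(cfg)
  st$age <- c(0, 0)
  n0 <- nrow(st$positions)
  st2 <- grow_and_divide(st, elapsed = cfg$tau * 0.999)
  expect_equal(sum(st2$cell_id == 1), 31)   # floor(16 * (1 + 0.999))
  # a full cycle doubles the elements, then divides them without loss
  st3 <- grow_and_divide(st, elapsed = cfg$tau)
  expect_equal(length(st3$cell_type), 4L)
  expect_equal(nrow(st3$positions), 2L * n0)   # division conserves elements
  # daughters within one element of each other
  counts <- table(st3$cell_id)
  expect_lte(abs(counts[["1"]] - counts[["3"]]), 1)
  # type inheritance
  expect_equal(st3$cell_type[3], st3$cell_type[1])
  expect_equal(st3$cell_type[4], st3$cell_type[2])
})

test_that("division cap holds the cell count and full doublings keep the ratio", {
  # full doubling 4 -> 8 preserves the 50/50 ratio exactly (every cell
  # divides once); a cap that interrupts a doubling freezes the count
  cfg <- sim_config(n_start = 4L, n_end = 8L, seed = 6, n_elements_per_cell = 16L)
  st <- init_state(cfg)
  for (k in 1:3) st <- grow_and_divide(st, elapsed = cfg$tau)
  expect_equal(length(st$cell_type), 8L)
  expect_equal(mean(st$cell_type == "PrE"), 0.5)
  cfg2 <- sim_config(n_start = 4L, n_end = 6L, seed = 6, n_elements_per_cell = 16L)
  st2 <- init_state(cfg2)
  for (k in 1:4) st2 <- grow_and_divide(st2, elapsed = cfg2$tau)
  expect_equal(length(st2$cell_type), 6L)
})

test_that("a relaxed cell is quasi-spherical", {
  cfg <- sim_config(n_start = 1L, n_end = 1L, seed = 3)
  st <- relax_state(init_state(cfg), duration = 4)
  ctr <- colMeans(st$positions)
  fl <- identify_cortex_elements(st$positions)
  r <- sqrt(rowSums(sweep(st$positions[fl, ], 2, ctr)^2))
  expect_lt(sd(r) / mean(r), 0.10)
})

test_that("tension modulation raises the temporal radius variance of a cell", {
  radial_var <- function(delta, seed = 12) {
    cfg <- sim_config(n_start = 1L, n_end = 1L, seed = seed, delta_epi = delta)
    st <- relax_state(init_state(cfg), duration = 2)
    eff <- fluctsort:::effective_config(cfg)
    dirs <- fluctsort:::fibonacci_directions(32L)
    rho <- matrix(NA_real_, 32L, 21L)
    pos <- st$positions; t <- 0
    for (i in 1:21) {
      if (i > 1) {
        r <- fluctsort:::cpp_sem_advance(pos, st$cell_id, fluctsort:::unique_types(st),
                                         st$phase, eff, t,
                                         as.integer(round(cfg$tau / 40 / cfg$dt)),
                                         cfg$rebuild_every)
        pos <- r$positions
        t <- r$time
      }
      v <- sweep(pos, 2, colMeans(pos))
      rr <- sqrt(rowSums(v^2))
      bin <- max.col((v / rr) %*% t(dirs))
      rho[, i] <- tapply(rr, factor(bin, levels = 1:32), max)
    }
    rho <- rho[stats::complete.cases(rho), , drop = FALSE]
    mean(apply(rho, 1, stats::var))
  }
  expect_gt(radial_var(0.7), 3 * radial_var(0))
})
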