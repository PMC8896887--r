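mixture_mesh <- function(n = 36, seed = 2, p0_pair = c(3.65, 4.05)) {
  mx <- make_vertex_mixture(n, p0_pair = p0_pair, seed = seed)
  build_vertex_mesh(mx$centers, mx$box, p0 = mx$p0, subtype = mx$subtype)
}

test_that("shape indices match closed forms and scale invariance", {
  expect_equal(shape_index_2d(2 * pi, pi), 2 * sqrt(pi))
  expect_equal(round(shape_index_2d(2 * pi, pi), 2), 3.54)
  expect_equal(shape_index_2d(4, 1), 4)
  expect_equal(shape_index_2d(5, 1), 5)          # 2 x 0.5 rectangle
  expect_equal(shape_index_3d(4 * pi, 4 * pi / 3), 4 * pi / (4 * pi / 3)^(2 / 3))
  expect_equal(shape_index_3d(6, 1), 6)
  lam <- 2.7
  expect_equal(shape_index_3d(lam^2 * 5, lam^3 * 0.9), shape_index_3d(5, 0.9))
  expect_error(shape_index_2d(-1, 1), "positive")
  expect_error(shape_index_3d(1, 0), "positive")
})

test_that("the Voronoi mesh is confluent and zero-energy at its targets", {
  mesh <- mixture_mesh(36, 2)
  g <- mesh_geometry(mesh)
  expect_equal(sum(g$area), mesh$box^2, tolerance = 1e-8)
  # every cell at its preferred geometry gives exactly zero energy
  m0 <- mesh
  m0$A0 <- g$area
  m0$P0 <- g$perimeter
  expect_equal(tissue_energy(m0), 0)
  expect_gte(tissue_energy(mesh), 0)
})

test_that("analytic gradient matches central finite differences", {
  mesh <- mixture_mesh(25, 4)
  G <- tissue_gradient(mesh)
  set.seed(1)
  for (i in sample(nrow(mesh$vertices), 4)) for (d in 1:2) {
    h <- 1e-6
    m1 <- mesh; m1$vertices[i, d] <- m1$vertices[i, d] + h
    m2 <- mesh; m2$vertices[i, d] <- m2$vertices[i, d] - h
    m1 <- fluctsort:::refresh_offsets(m1)
    m2 <- fluctsort:::refresh_offsets(m2)
    fd <- (tissue_energy(m1) - tissue_energy(m2)) / (2 * h)
    expect_equal(G[i, d], fd, tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("edge tension has the right zeros, signs and derivative", {
  mesh <- mixture_mesh(16, 5)
  g <- mesh_geometry(mesh)
  # set preferred perimeter to actual: all tensions zero
  m0 <- mesh
  m0$P0 <- g$perimeter
  et0 <- edge_tension(m0)
  expect_true(all(abs(et0$tension) < 1e-12))
  # every cell under-stretched (P < P0): all interior edges extensile
  m1 <- mesh
  m1$P0 <- g$perimeter + 1
  et1 <- edge_tension(m1)
  expect_true(all(et1$tension[!is.na(et1$cell_b)] < 0))
  # finite difference of the energy under an isolated edge-length change
  et <- edge_tension(mesh)
  k <- which(!is.na(et$cell_b))[3]
  dEdl <- function(dl) {
    P <- g$perimeter
    P[et$cell_a[k]] <- P[et$cell_a[k]] + dl
    P[et$cell_b[k]] <- P[et$cell_b[k]] + dl
    sum(mesh$KA * (g$area - mesh$A0)^2 + mesh$KP * (P - mesh$P0)^2)
  }
  h <- 1e-6
  expect_equal(et$tension[k], (dEdl(h) - dEdl(-h)) / (2 * h), tolerance = 1e-6)
})

test_that("FIRE descends monotonically within topology segments and stops at rest", {
  mesh <- mixture_mesh(25, 6)
  rel <- fire_minimize(mesh, tol = 5e-3, max_iter = 2000)
  expect_true(attr(rel, "converged"))
  e <- attr(rel, "energy")
  seg_ok <- TRUE
  for (i in seq_len(length(e) - 1)) {
    if (!is.na(e[i]) && !is.na(e[i + 1]) && e[i + 1] > e[i] + 1e-9) seg_ok <- FALSE
  }
  expect_true(seg_ok)
  expect_lt(tail(e[!is.na(e)], 1), e[1])
  # an already relaxed mesh stays put
  rel2 <- fire_minimize(rel, tol = 5e-3, max_iter = 200)
  expect_lt(max(abs(rel2$vertices - rel$vertices)), 1e-6)
})

test_that("FIRE reaches the same minimum as plain gradient descent on a small mesh", {
  # compare the two descent algorithms inside one topological basin: start
  # from a relaxed mesh (T1s already resolved) perturbed by a small kick
  base <- fire_minimize(mixture_mesh(16, 7, p0_pair = c(3.7, 3.7)),
                        tol = 1e-3, max_iter = 4000)
  set.seed(3)
  kick <- base
  kick$vertices <- kick$vertices + matrix(rnorm(length(kick$vertices), 0, 0.02), ncol = 2)
  kick <- fluctsort:::refresh_offsets(kick)
  fire <- fire_minimize(kick, tol = 1e-4, max_iter = 4000, t1_every = 1e9)
  gd <- kick
  for (it in 1:20000) {
    G <- tissue_gradient(gd)
    if (max(sqrt(rowSums(G^2))) < 1e-4) break
    gd$vertices <- gd$vertices - 3e-3 * G
    gd <- fluctsort:::refresh_offsets(gd)
  }
  e_f <- tissue_energy(fire)
  e_g <- tissue_energy(gd)
  expect_equal(e_f, e_g, tolerance = 1e-4 * max(e_g, 1e-8))
})
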