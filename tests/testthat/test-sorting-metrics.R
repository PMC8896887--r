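test_that("external surface fraction hits the shell endpoints exactly", {
  # explicit two-shell geometry: inner EPI core, complete PrE shell
  set.seed(1)
  shell <- 3 * fluctsort:::fibonacci_directions(20)
  core_pts <- matrix(rnorm(18, 0, 0.3), 6)
  agg <- labeled_aggregate(rbind(core_pts, shell),
                           c(rep("EPI", 6), rep("PrE", 20)))
  expect_equal(external_surface_fraction(agg), 1.0)
  agg_inv <- labeled_aggregate(rbind(core_pts, shell),
                               c(rep("PrE", 6), rep("EPI", 20)))
  expect_equal(external_surface_fraction(agg_inv), 0.0)
})

test_that("random labels give XS centred on the PrE share", {
  agg <- make_aggregate(16, "random", seed = 2)
  counts <- external_elements(agg)
  total <- sum(counts)
  set.seed(9)
  xs <- replicate(1000, sum(counts[sample.int(16, 8)]) / total)
  se <- sd(xs) / sqrt(1000)
  expect_lt(abs(mean(xs) - 0.5), 3 * se + 1e-12)
})

test_that("randomization null matches exact enumeration on 8 cells", {
  agg <- make_aggregate(8, "random", prE_fraction = 0.5, seed = 3)
  counts <- as.numeric(external_elements(agg))
  total <- sum(counts)
  cmb <- combn(8, 4)
  xs_exact <- apply(cmb, 2, function(v) sum(counts[v]) / total)
  mu_exact <- mean(xs_exact)
  sd_exact <- sqrt(mean((xs_exact - mu_exact)^2))
  nn <- randomization_null(agg, n_shuffles = 100000, seed = 11)
  se_mu <- sd_exact / sqrt(nn$n_shuffles)
  expect_lt(abs(nn$mu - mu_exact), 4 * se_mu)
  expect_equal(nn$sigma, sd_exact, tolerance = 0.03 * sd_exact)
  # hypergeometric closed form for the mean of a count-weighted share
  expect_equal(mu_exact, 0.5, tolerance = 1e-12)
})

test_that("null is invariant to relabeling cell order", {
  agg <- make_aggregate(10, "random", seed = 4)
  n1 <- randomization_null(agg, 20000, seed = 5)
  perm <- sample(10)
  agg2 <- labeled_aggregate(agg$positions[perm, ], agg$cell_type[perm])
  n2 <- randomization_null(agg2, 20000, seed = 5)
  expect_equal(n1$mu, n2$mu, tolerance = 0.01)
  expect_equal(n1$sigma, n2$sigma, tolerance = 0.05 * n1$sigma)
})

test_that("sorting index has its defining anchor points", {
  expect_equal(sorting_index(0.5, 0.5, 0.05), 0)
  expect_equal(sorting_index(0.7, 0.5, 0.05), 1)
  expect_equal(sorting_index(0.3, 0.5, 0.05), -1)
  expect_error(sorting_index(0.5, 0.5, 0), "positive")
})

test_that("SI is invariant under rigid motion of the aggregate", {
  agg <- make_aggregate(14, "core_shell", seed = 6)
  si0 <- sorting_index_of(agg, n_shuffles = 20000, seed = 7)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pos2 <- agg$positions %*% t(Rz) + matrix(c(5, -3, 2), nrow(agg$positions), 3, byrow = TRUE)
  agg2 <- labeled_aggregate(pos2, agg$cell_type)
  si1 <- sorting_index_of(agg2, n_shuffles = 20000, seed = 7)
  expect_equal(si1$XS, si0$XS, tolerance = 0.05)
  expect_equal(si1$SI, si0$SI, tolerance = 0.2)
})

test_that("synthetic arrangements score at the SI landmarks", {
  # at blastocyst-scale aggregate sizes a complete core-shell crosses the
  # complete-sorting threshold; small aggregates saturate below it because
  # half the cells cannot cover the whole exterior
  core <- make_aggregate(40, "core_shell", seed = 8)
  expect_gte(sorting_index_of(core, n_shuffles = 20000, seed = 9)$SI, 1.0)
  inv <- make_aggregate(40, "inverted", seed = 8)
  expect_lte(sorting_index_of(inv, n_shuffles = 20000, seed = 9)$SI, -1.0)
})

test_that("demixing parameter has exact endpoints and label symmetry", {
  # two separated half-lattices on a long strip: DP -> 1
  grid <- expand.grid(x = 1:20, y = 1:4)
  pos <- as.matrix(grid)
  types <- ifelse(grid$x <= 10, "A", "B")
  pairs <- which(as.matrix(dist(pos, method = "manhattan")) == 1 &
                   upper.tri(matrix(0, nrow(pos), nrow(pos))), arr.ind = TRUE)
  adj <- unname(pairs)
  dp <- demixing_parameter(adj, types)
  expect_gt(dp, 0.8)
  # label swap symmetry
  types2 <- ifelse(types == "A", "B", "A")
  expect_equal(as.numeric(demixing_parameter(adj, types2)), as.numeric(dp))
  # random labels average to ~0 after clipping at zero
  set.seed(10)
  dps <- replicate(200, {
    ty <- sample(types)
    attr(demixing_parameter(adj, ty), "f_same") -
      attr(demixing_parameter(adj, ty), "f_rand")
  })
  expect_lt(abs(mean(dps)), 3 * sd(dps) / sqrt(200))
})

test_that("demixing parameter on a 2x2 lattice matches hand enumeration", {
  pos <- expand.grid(x = 1:2, y = 1:2)
  adj <- rbind(c(1, 2), c(3, 4), c(1, 3), c(2, 4))
  # 50/50 labelings: diagonal pairs give f_same = 0; side pairs give 1/2
  labelings <- list(c("A","A","B","B"), c("A","B","A","B"), c("A","B","B","A"))
  f_rand <- (2 * 1 + 2 * 1) / (4 * 3)
  dps <- vapply(labelings, function(ty)
    as.numeric(demixing_parameter(adj, ty)), 0)
  expect_equal(dps[1], (0.5 - f_rand) / (1 - f_rand))   # horizontal split
  expect_equal(dps[2], (0.5 - f_rand) / (1 - f_rand))   # vertical split
  expect_equal(dps[3], 0)                               # checkerboard clips to 0
})

test_that("radial enrichment normalizes correctly and scales", {
  # concentric shells: labels at radius 2 (n), others at 1 (n)
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  pos <- rbind(cbind(2 * cos(th), 2 * sin(th)), cbind(cos(th), sin(th)))
  w <- c(rep(1, 8), rep(0, 8))
  expect_equal(radial_enrichment(pos, w), 2 / 1.5, tolerance = 1e-10)
  # uniform labels -> 1
  expect_equal(radial_enrichment(pos, rep(1, 16)), 1)
  # scaling invariance
  expect_equal(radial_enrichment(5 * pos, w), radial_enrichment(pos, w))
  expect_error(radial_enrichment(pos, rep(0, 16)), "all signal")
})

test_that("tertile split keeps only the top half and scores each group", {
  set.seed(11)
  pos <- matrix(rnorm(60 * 3), 60)
  expr <- runif(60)
  out <- radial_enrichment_tertiles(pos, expr)
  expect_equal(out$group, c("low", "mid", "high"))
  expect_true(all(is.finite(out$R)))
})
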