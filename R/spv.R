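#' Self-propelled-Voronoi configuration
#'
#' Parameters of the 2D self-propelled Voronoi dynamics used for the
#' demixing runs: cell centres move down the shape-energy gradient of
#' their instantaneous Voronoi cell plus a persistent self-propulsion of
#' speed `v0` whose direction diffuses rotationally with coefficient `Dr`.
#' With area stiffness and preferred area of one, the natural timescale is
#' one, and the timestep is `0.01` of it.
#'
#' @param n_cells Number of cells.
#' @param p0_pair Preferred shape indices of the two subtypes (default
#'   the solid-like/fluid-like pair `c(3.65, 4.05)`; the 3D analogue
#'   presets `c(5.20, 6.00)`, `c(5.35, 6.15)`, `c(5.50, 6.30)` are
#'   recorded in [spv_presets_3d()]).
#' @param v0 Self-propulsion speed (default 0.1).
#' @param Dr Rotational diffusion coefficient (default 1.0).
#' @param dt Timestep (default 0.01).
#' @param KA,KP Area and perimeter moduli (default 1).
#' @param box Box side (default `sqrt(n_cells)`, unit mean cell area).
#' @param duration Total simulated time.
#' @param seed Integer seed.
#' @return A list of class `spv_config`.
#' @export
spv_config <- function(n_cells = 64L, p0_pair = c(3.65, 4.05), v0 = 0.1,
                       Dr = 1.0, dt = 0.01, KA = 1, KP = 1, box = NULL,
                       duration = 100, seed = 1L) {
  chk_num(v0, "v0", 0)
  chk_num(Dr, "Dr", 0, strict_lower = TRUE)
  chk_num(dt, "dt", 0, strict_lower = TRUE)
  if (is.null(box)) box <- sqrt(n_cells)
  structure(list(n_cells = as.integer(n_cells), p0_pair = p0_pair, v0 = v0,
                 Dr = Dr, dt = dt, KA = KA, KP = KP, box = box,
                 duration = duration, seed = as.integer(seed)),
            class = "spv_config")
}

#' Recorded 3D self-propelled-Voronoi preset shape-index pairs
#'
#' The 3D demixing analyses use pairs of preferred 3D shape indices at a
#' fixed disparity with increasing mean fluidity; they are kept here as
#' reference presets (the dynamics in this package are the 2D analogue).
#'
#' @return Data frame of preset pairs and mean fluidity.
#' @export
spv_presets_3d <- function() {
  data.frame(solid = c(5.20, 5.35, 5.50), fluid = c(6.00, 6.15, 6.30),
             mean_s0 = c(5.60, 5.75, 5.90))
}

#' Advance self-propelled Voronoi dynamics
#'
#' Runs `n_steps` of the SPV update: re-tessellate, move every centre by
#' `dt * (F_shape + v0 * n_i)` and diffuse the polarity angles. Positions
#' are wrapped into the periodic box (set `wrap = FALSE` with
#' `shape_forces = FALSE` for free-particle displacement statistics).
#'
#' @param centers n x 2 centre matrix.
#' @param polarity Polarity angles (radians), length n.
#' @param cfg An `spv_config`.
#' @param p0 Per-cell preferred shape index (length n).
#' @param n_steps Steps to advance.
#' @param seed Seed of this block's rotational noise (defaults to
#'   `cfg$seed`).
#' @param shape_forces Include Voronoi shape forces (default TRUE).
#' @param wrap Wrap positions into the box (default TRUE).
#' @return List with advanced `centers` and `polarity`.
#' @export
spv_step <- function(centers, polarity, cfg, p0, n_steps = 1L,
                     seed = cfg$seed, shape_forces = TRUE, wrap = TRUE) {
  stopifnot(inherits(cfg, "spv_config"))
  centers <- as.matrix(centers)
  n <- nrow(centers)
  stopifnot(length(polarity) == n, length(p0) == n)
  if (shape_forces && !wrap) stop("shape forces require wrapped positions")
  # coincident centres destabilize the tessellation: jitter with a warning
  d <- as.matrix(dist(centers))
  diag(d) <- Inf
  if (min(d) < 1e-9 * cfg$box) {
    warning("coincident centres jittered")
    centers <- centers + matrix(rnorm(2 * n, 0, 1e-6 * cfg$box), n, 2)
  }
  A0 <- rep(cfg$box^2 / n, n)
  P0 <- p0 * sqrt(A0)
  margin <- 3 * sqrt(cfg$box^2 / n)
  res <- cpp_spv_run(centers, polarity, A0, P0, cfg$KA, cfg$KP, cfg$box,
                     cfg$v0, cfg$Dr, cfg$dt, 1.0, as.integer(n_steps),
                     shape_forces, margin, as.integer(seed), wrap)
  list(centers = res$centers, polarity = res$theta)
}

#' Voronoi adjacency and cell geometry in a periodic box
#'
#' @param centers n x 2 centre matrix.
#' @param box Box side.
#' @return List with per-cell `area`, `perimeter` and a two-column
#'   `neighbors` matrix of adjacent cell pairs.
#' @export
voronoi_adjacency <- function(centers, box) {
  centers <- as.matrix(centers)
  margin <- 3 * sqrt(box^2 / nrow(centers))
  cpp_voronoi_geom(centers, box, margin)
}

#' Run a demixing simulation
#'
#' Starts from a randomly mixed binary configuration
#' ([make_vertex_mixture()]), advances the self-propelled Voronoi dynamics
#' and records the demixing parameter on the instantaneous Voronoi
#' adjacency at (approximately) log-spaced times. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg An `spv_config`.
#' @param n_records Number of recording times (log-spaced from the first
#'   percent of the run to its end).
#' @return List of class `demixing_run`: `dp` (data.frame time, DP),
#'   `centers`, `subtype`, `cfg`.
#' @export
run_demixing <- function(cfg, n_records = 12L) {
  stopifnot(inherits(cfg, "spv_config"))
  mix <- make_vertex_mixture(cfg$n_cells, cfg$p0_pair, box = cfg$box,
                             seed = cfg$seed)
  centers <- mix$centers
  polarity <- with_seed(cfg$seed + 13L, runif(cfg$n_cells, 0, 2 * pi))
  p0 <- mix$p0
  total_steps <- max(1L, as.integer(round(cfg$duration / cfg$dt)))
  rec_steps <- unique(c(0L, round(exp(seq(log(max(1, total_steps / 100)),
                                          log(total_steps),
                                          length.out = n_records)))))
  rec_steps <- as.integer(sort(unique(pmin(rec_steps, total_steps))))
  dp_of <- function(centers) {
    adj <- voronoi_adjacency(centers, cfg$box)
    as.numeric(demixing_parameter(adj$neighbors, mix$subtype))
  }
  out <- data.frame(time = numeric(0), DP = numeric(0))
  done <- 0L
  for (k in seq_along(rec_steps)) {
    todo <- rec_steps[k] - done
    if (todo > 0L) {
      st <- spv_step(centers, polarity, cfg, p0, n_steps = todo,
                     seed = cfg$seed + 1000L + k)
      centers <- st$centers
      polarity <- st$polarity
      done <- rec_steps[k]
    }
    out <- rbind(out, data.frame(time = done * cfg$dt, DP = dp_of(centers)))
  }
  structure(list(dp = out, centers = centers, subtype = mix$subtype,
                 cfg = cfg), class = "demixing_run")
}
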