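#' Simulation configuration for the subcellular-element sorting model
#'
#' Collects every mechanical, fluctuation, growth and integration parameter
#' of the 3D force-based cell-sorting simulator. Cells are clouds of
#' elements interacting through Morse potentials; a Delaunay network over
#' each cell's cortex elements carries a constant-magnitude cortical
#' tension, locally rescaled at cell-cell interfaces (affinity asymmetry
#' `beta`) and modulated sinusoidally per cortex element (surface
#' fluctuations, amplitudes `delta_epi` and `(1+epsilon)*delta_epi` for the
#' two lineages).
#'
#' Units are nondimensional: one length unit is the cell radius at birth
#' (about 7.2 um for ICM progenitors), forces are scaled to the Morse
#' depth, and `tau` is the cell-cycle time in simulation time units.
#'
#' @param gamma_cm Cortical tension magnitude (default 1.4).
#' @param adhesion_AM Inter-cell adhesion magnitude (default 0.3, about
#'   0.2 * gamma_cm).
#' @param beta Affinity ratio in (0, 1]: the EPI::EPI interfacial tension
#'   relative to PrE::PrE. 1 means no asymmetry.
#' @param epsilon PrE-to-EPI fluctuation excess (>= 0); PrE amplitude is
#'   `(1 + epsilon) * delta_epi`.
#' @param delta_epi Base (EPI) fluctuation amplitude, a dimensionless
#'   fraction of the cortical tension.
#' @param tau Cell-cycle time (simulation time units); the tension
#'   modulation has period `tau / 10`.
#' @param morse_depth,morse_range,morse_req Morse potential constants;
#'   defaults give an equilibrium spacing `2 * cell_radius /
#'   n_elements_per_cell^(1/3)` and range `2 / morse_req`.
#' @param n_elements_per_cell Elements per cell at birth (default 64).
#' @param drag Mobility coefficient of the overdamped integrator.
#' @param dt Timestep.
#' @param n_start,n_end Cell counts at the start and the division cap
#'   (defaults 10 and 50).
#' @param prE_fraction Fraction of PrE cells (default 0.5).
#' @param cell_radius Cell radius at birth (1 simulation length unit).
#' @param seed Integer seed.
#' @param interface_scale Cortical-tension scale at cell-cell interfaces
#'   relative to the free surface (< 1: the cortex is downregulated at
#'   contacts, which is what lets adhesive contacts spread).
#' @param beta_gain Gain mapping the requested affinity ratio onto the
#'   EPI::EPI interfacial-tension scale (`s_EE = interface_scale * (1 -
#'   beta_gain * (1 - beta))`). At the element resolution used here the
#'   emergent contact-angle readout compresses the cosine ratio towards 1,
#'   so the gain is set for a strong energetic differential rather than an
#'   exact angle-based round trip (see the methods vignette).
#' @param adhesion_gain Calibration of the inter-cell adhesive Morse well
#'   depth (`adhesion_AM * adhesion_gain`), set so doublets form stable
#'   contacts without freezing rearrangements.
#' @param cone_deg Cortex-identification cone half-angle (degrees).
#' @param rebuild_every Steps between cortex-network / pair-list rebuilds.
#' @param settle_frac Fraction of `tau` simulated after the division cap is
#'   reached, before the final snapshot.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(gamma_cm = 1.4, adhesion_AM = 0.3, beta = 1.0,
                       epsilon = 0, delta_epi = 1.0, tau = 20,
                       morse_depth = 0.5,
                       morse_req = NULL, morse_range = NULL,
                       n_elements_per_cell = 64L, drag = 1, dt = 0.001,
                       n_start = 10L, n_end = 50L, prE_fraction = 0.5,
                       cell_radius = 1, seed = 1L,
                       interface_scale = 0.4,
                       beta_gain = 2, adhesion_gain = 3,
                       cone_deg = 25,
                       tension_max_edge = NULL, cutoff = NULL,
                       rebuild_every = 20L, settle_frac = 0.25) {
  if (is.null(morse_req)) morse_req <- 2 * cell_radius / n_elements_per_cell^(1 / 3)
  if (is.null(morse_range)) morse_range <- 2 / morse_req
  if (is.null(tension_max_edge)) tension_max_edge <- 2.0 * morse_req
  if (is.null(cutoff)) cutoff <- 1.5 * morse_req
  cfg <- list(gamma_cm = gamma_cm, adhesion_AM = adhesion_AM, beta = beta,
              epsilon = epsilon, delta_epi = delta_epi, tau = tau,
              morse_depth = morse_depth, morse_range = morse_range,
              morse_req = morse_req,
              n_elements_per_cell = as.integer(n_elements_per_cell),
              drag = drag, dt = dt,
              n_start = as.integer(n_start), n_end = as.integer(n_end),
              prE_fraction = prE_fraction, cell_radius = cell_radius,
              seed = as.integer(seed), interface_scale = interface_scale,
              beta_gain = beta_gain,
              adhesion_gain = adhesion_gain,
              cone_deg = cone_deg, tension_max_edge = tension_max_edge,
              cutoff = cutoff,
              rebuild_every = as.integer(rebuild_every),
              settle_frac = settle_frac)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_num(cfg$beta, "beta", 0, 1, strict_lower = TRUE)
  chk_num(cfg$epsilon, "epsilon", 0)
  chk_num(cfg$dt, "dt", 0, strict_lower = TRUE)
  chk_num(cfg$tau, "tau", 0, strict_lower = TRUE)
  chk_num(cfg$prE_fraction, "prE_fraction", 0, 1, strict_lower = TRUE)
  if (cfg$prE_fraction >= 1) stop("'prE_fraction' must be < 1")
  for (nm in c("gamma_cm", "adhesion_AM", "delta_epi", "morse_depth", "drag"))
    chk_num(cfg[[nm]], nm, 0)
  if (cfg$n_start > cfg$n_end) stop("'n_start' must be <= 'n_end'")
  if (cfg$n_start < 1L) stop("'n_start' must be >= 1")
  if (cfg$n_elements_per_cell < 8L) stop("need at least 8 elements per cell")
  structure(cfg, class = "sim_config")
}

#' Read / write a simulation configuration as JSON
#'
#' Round-trips every [sim_config()] field through structured text; unknown
#' keys in the file are rejected.
#'
#' @param path File path.
#' @return For `read_sim_config`, a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, x)
}

#' @rdname read_sim_config
#' @param cfg A `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Effective config passed to the C++ kernels. Cortical tension is reduced
# to interface_scale at every cell-cell contact; the user-facing affinity
# ratio scales the EPI::EPI interface relative to PrE::PrE (through the
# calibrated beta_gain), heterotypic contacts sit midway.
effective_config <- function(cfg) {
  out <- unclass(cfg)
  out$s_pp <- cfg$interface_scale
  out$s_ee <- cfg$interface_scale * max(0.05, 1 - cfg$beta_gain * (1 - cfg$beta))
  out$s_het <- 0.5 * (out$s_ee + out$s_pp)
  out
}

#' Morse pair force
#'
#' Signed radial force \eqn{-dU/dr} for the Morse potential
#' \eqn{U(r) = D (e^{-2a(r - r_e)} - 2 e^{-a(r - r_e)})}: positive
#' (repulsive) below the equilibrium separation \eqn{r_e}, attractive and
#' decaying beyond it.
#'
#' @param r Separation distance (> 0; vectorized).
#' @param depth Well depth D.
#' @param range Inverse-range parameter a.
#' @param req Equilibrium separation.
#' @return Signed force, positive = repulsive.
#' @export
morse_pair_force <- function(r, depth, range, req) {
  if (any(r <= 0)) stop("invalid geometry: separation must be positive")
  e1 <- exp(-range * (r - req))
  2 * depth * range * (e1^2 - e1)
}

#' Sinusoidal cortical-tension modulation
#'
#' Multiplicative factor `1 + delta * sin(2 * pi * 10 * t / tau + phase)`
#' applied to the cortical-tension forces on a cortex element: ten
#' fluctuation periods per cell cycle, with a per-element random phase
#' fixed at element creation.
#'
#' @param t Time (vectorized).
#' @param tau Cell-cycle time (> 0).
#' @param phase Phase offset in radians.
#' @param delta Modulation amplitude (>= 0).
#' @return The multiplicative factor.
#' @export
tension_modulation <- function(t, tau, phase, delta) {
  chk_num(tau, "tau", 0, strict_lower = TRUE)
  if (any(delta < 0)) stop("'delta' must be >= 0")
  1 + delta * sin(2 * pi * 10 * t / tau + phase)
}

#' Flag the cortex (boundary) elements of one cell
#'
#' An element is cortical when no element of the same cell lies radially
#' beyond it within a cone (half-angle `cone_deg`) about its direction from
#' the cell centroid; all convex-hull vertices of the element cloud are
#' additionally flagged.
#'
#' @param cell_positions Element coordinate matrix (m x 3) of one cell.
#' @param cone_deg Cone half-angle in degrees (default 25).
#' @return Logical vector of cortex flags.
#' @export
identify_cortex_elements <- function(cell_positions, cone_deg = 25) {
  cell_positions <- as.matrix(cell_positions)
  if (nrow(cell_positions) == 0L) stop("need at least one element")
  if (ncol(cell_positions) != 3L) stop("positions must be m x 3")
  if (nrow(cell_positions) == 1L) return(TRUE)
  cpp_identify_cortex(cell_positions, cone_deg)
}

#' Delaunay cortex network of one cell
#'
#' Edge set of the 3D Delaunay triangulation of a cell's cortex elements —
#' the nearest-neighbour network along which cortical tension acts.
#' Coplanar element sets fall back to a 2D triangulation in the best-fit
#' plane (with a warning).
#'
#' @param cortex_positions Cortex element coordinates (m x 3, m >= 4 for a
#'   3D triangulation).
#' @param max_edge Optional length cutoff; edges longer than this are
#'   dropped (the force kernel uses `2.5 * morse_req` to exclude interior
#'   diagonals of the shell).
#' @return Two-column integer matrix of element index pairs (i < j), with
#'   attribute `planar` TRUE if the planar fallback was used.
#' @export
build_cortex_network <- function(cortex_positions, max_edge = Inf) {
  p <- as.matrix(cortex_positions)
  if (nrow(p) < 4L) stop("need at least 4 cortex elements")
  planar <- FALSE
  edges <- tryCatch(cpp_delaunay3(p)$edges, error = function(e) {
    if (!grepl("coplanar|degenerate", conditionMessage(e))) stop(e)
    NULL
  })
  if (is.null(edges)) {
    warning("degenerate (coplanar) cortex; falling back to planar triangulation")
    planar <- TRUE
    ctr <- colMeans(p)
    sv <- svd(sweep(p, 2L, ctr))
    plane <- sweep(p, 2L, ctr) %*% sv$v[, 1:2]
    tri <- cpp_delaunay2(plane)
    edges <- unique(rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)]))
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
  }
  if (is.finite(max_edge)) {
    len <- sqrt(rowSums((p[edges[, 1], , drop = FALSE] - p[edges[, 2], , drop = FALSE])^2))
    edges <- edges[len <= max_edge, , drop = FALSE]
  }
  colnames(edges) <- c("i", "j")
  attr(edges, "planar") <- planar
  edges
}

#' Initialize an aggregate state
#'
#' Packs `n_start` cells (alternating EPI/PrE labels shuffled at the given
#' fraction) into a ball and fills each with `n_elements_per_cell` elements;
#' cell ages are staggered uniformly over the cycle so divisions
#' desynchronize. Run [relax_state()] before production stepping.
#'
#' @param config A `sim_config`.
#' @return A list of class `aggregate_state`: `positions` (n x 3),
#'   `cell_id`, `phase` (per element), `cell_type`, `age`, `birth_n` (per
#'   cell), `time`, `config`.
#' @export
init_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_c <- config$n_start
    R <- config$cell_radius
    # pack cell centres
    ctrs <- matrix(0, n_c, 3)
    if (n_c > 1L) {
      R_agg <- 1.15 * R * n_c^(1 / 3)
      repeat {
        k <- 0L; tries <- 0L
        while (k < n_c && tries < 20000L) {
          p <- runif(3, -1, 1)
          if (sum(p^2) <= 1) {
            p <- p * R_agg
            if (k == 0L ||
                min(sqrt(rowSums(sweep(ctrs[seq_len(k), , drop = FALSE], 2L, p)^2))) >= 1.7 * R) {
              k <- k + 1L
              ctrs[k, ] <- p
            }
          }
          tries <- tries + 1L
        }
        if (k == n_c) break
        R_agg <- R_agg * 1.1
      }
    }
    n_pre <- round(config$prE_fraction * n_c)
    types <- rep("EPI", n_c)
    types[sample.int(n_c, n_pre)] <- "PrE"
    m <- config$n_elements_per_cell
    pos <- matrix(0, n_c * m, 3)
    cell_id <- rep(seq_len(n_c), each = m)
    d_min <- 0.55 * config$morse_req   # avoid deep Morse overlaps at start
    for (c in seq_len(n_c)) {
      pts <- matrix(0, m, 3)
      k <- 0L; tries <- 0L
      while (k < m) {
        p <- runif(3, -1, 1)
        tries <- tries + 1L
        if (tries > 20000L) { d_min <- d_min * 0.8; tries <- 0L }
        if (sum(p^2) > 1) next
        p <- p * 0.9 * R
        if (k > 0L &&
            min(sqrt(rowSums(sweep(pts[seq_len(k), , drop = FALSE], 2L, p)^2))) < d_min) next
        k <- k + 1L
        pts[k, ] <- p
      }
      pos[cell_id == c, ] <- sweep(pts, 2L, ctrs[c, ], `+`)
    }
    state <- list(positions = pos, cell_id = cell_id,
                  phase = runif(n_c * m, 0, 2 * pi),
                  cell_type = types,
                  age = runif(n_c, 0, config$tau),
                  birth_n = rep(m, n_c),
                  time = 0, config = config)
    class(state) <- "aggregate_state"
    state
  })
}

#' Relax an aggregate without fluctuations
#'
#' Advances the state with fluctuation amplitudes set to zero (and a
#' ramped-up timestep at first) to dissipate the random initial overlaps
#' before production dynamics.
#'
#' @param state An `aggregate_state`.
#' @param duration Relaxation time (simulation units).
#' @return The relaxed state (time is not advanced).
#' @export
relax_state <- function(state, duration = 2) {
  cfg <- state$config
  quiet <- cfg
  quiet$delta_epi <- 0
  eff <- effective_config(quiet)
  t_saved <- state$time
  # gentle ramp to absorb initialization overlaps
  for (f in c(0.005, 0.02, 0.1, 0.5)) {
    eff$dt <- cfg$dt * f
    res <- cpp_sem_advance(state$positions, state$cell_id,
                           unique_types(state),
                           state$phase, eff, state$time,
                           100L, cfg$rebuild_every)
    state$positions <- res$positions
  }
  eff$dt <- cfg$dt
  nsteps <- max(1L, as.integer(round(duration / cfg$dt)))
  res <- cpp_sem_advance(state$positions, state$cell_id,
                         as.integer(unique_types(state)),
                         state$phase, eff, state$time, nsteps, cfg$rebuild_every)
  state$positions <- res$positions
  state$time <- t_saved
  state
}

# integer types (0 = EPI, 1 = PrE) indexed by cell id
unique_types <- function(state) as.integer(state$cell_type == "PrE")

#' Compute per-element forces of the current state
#'
#' Builds the cortex flags, Delaunay tension network, contact labels and
#' Morse pair list afresh and returns the total force on every element:
#' intra-cell Morse forces, inter-cell cortex adhesion (Morse scaled by
#' `adhesion_AM`), constant-magnitude cortical tension on network edges
#' with interfacial scaling, and the per-element sinusoidal tension
#' modulation. All pairwise contributions are antisymmetric.
#'
#' @param state An `aggregate_state`.
#' @param config Optional `sim_config` override (defaults to the state's).
#' @param time Evaluation time (defaults to the state's clock).
#' @return n x 3 force matrix with attributes `cortex` (flags), `edges`
#'   and `edge_scale` (the tension network used).
#' @export
compute_forces <- function(state, config = state$config, time = state$time) {
  eff <- effective_config(config)
  res <- cpp_sem_forces(state$positions, state$cell_id,
                        as.integer(state$cell_type == "PrE"),
                        state$phase, eff, time)
  out <- res$forces
  attr(out, "cortex") <- res$cortex
  attr(out, "edges") <- res$edges
  attr(out, "edge_scale") <- res$edge_scale
  out
}

#' One explicit overdamped step
#'
#' First-order update `x <- x + dt * F / drag`; errors if any element
#' would move farther than half the Morse equilibrium spacing in a single
#' step (timestep too large).
#'
#' @param state An `aggregate_state`.
#' @param forces n x 3 force matrix (see [compute_forces()]).
#' @param dt Timestep (defaults to the config's).
#' @param drag Mobility coefficient (defaults to the config's).
#' @return The advanced state (positions and time updated).
#' @export
step_overdamped <- function(state, forces, dt = state$config$dt,
                            drag = state$config$drag) {
  if (any(!is.finite(forces))) stop("non-finite forces")
  disp <- dt * forces / drag
  dmax <- max(sqrt(rowSums(disp^2)))
  if (dmax > 0.5 * state$config$morse_req)
    stop(sprintf("timestep too large: max displacement %.3g exceeds half the Morse spacing", dmax))
  state$positions <- state$positions + disp
  state$time <- state$time + dt
  state
}

#' Grow cells and perform symmetric divisions
#'
#' Advances cell ages by `elapsed`; each cell adds elements at a uniform
#' rate so its element count doubles over one cycle `tau`. At age `tau` a
#' cell splits by a plane of random orientation through its centroid into
#' two daughters of (near-)equal element count inheriting its type; the
#' division is skipped once the aggregate holds `n_end` cells.
#'
#' @param state An `aggregate_state`.
#' @param config Optional `sim_config` override.
#' @param elapsed Time to add to every cell age (default 0: only enforce
#'   targets at the current ages).
#' @return The updated state.
#' @export
grow_and_divide <- function(state, config = state$config, elapsed = 0) {
  cfg <- config
  state$age <- state$age + elapsed
  n_cells <- length(state$cell_type)
  # --- growth: linear doubling of element count over one cycle ---
  for (c in seq_len(n_cells)) {
    frac <- min(state$age[c] / cfg$tau, 1)
    target <- floor(state$birth_n[c] * (1 + frac))
    have <- sum(state$cell_id == c)
    if (have < target) {
      rows <- which(state$cell_id == c)
      add <- target - have
      src <- rows[sample.int(length(rows), add, replace = TRUE)]
      ctr <- colMeans(state$positions[rows, , drop = FALSE])
      inward <- ctr - state$positions[src, , drop = FALSE]
      nrm <- sqrt(rowSums(inward^2)) + 1e-9
      newp <- state$positions[src, , drop = FALSE] +
        0.4 * cfg$morse_req * inward / nrm +
        matrix(rnorm(3 * add, 0, 0.15 * cfg$morse_req), add, 3)
      state$positions <- rbind(state$positions, newp)
      state$cell_id <- c(state$cell_id, rep(c, add))
      state$phase <- c(state$phase, runif(add, 0, 2 * pi))
    }
  }
  # --- divisions ---
  for (c in seq_len(n_cells)) {
    if (state$age[c] < cfg$tau) next
    if (length(state$cell_type) >= cfg$n_end) {
      state$age[c] <- cfg$tau   # hold at the cap
      next
    }
    rows <- which(state$cell_id == c)
    ctr <- colMeans(state$positions[rows, , drop = FALSE])
    nrm <- rnorm(3)
    nrm <- nrm / sqrt(sum(nrm^2))
    proj <- as.numeric(sweep(state$positions[rows, , drop = FALSE], 2L, ctr) %*% nrm)
    ord <- rows[order(proj)]
    half <- length(ord) %/% 2L
    new_id <- length(state$cell_type) + 1L
    state$cell_id[ord[seq_len(half)]] <- new_id
    state$cell_type <- c(state$cell_type, state$cell_type[c])
    state$age[c] <- 0
    state$age <- c(state$age, 0)
    state$birth_n[c] <- length(ord) - half
    state$birth_n <- c(state$birth_n, half)
  }
  state
}

#' Run a full sorting simulation
#'
#' Evolves an aggregate from `n_start` to `n_end` cells under growth,
#' symmetric division, affinity asymmetry `beta` and differential surface
#' fluctuations `epsilon`, recording the sorting index at regular
#' snapshots. Deterministic given `config$seed`.
#'
#' @param config A `sim_config`.
#' @param snapshot_dt Time between sorting-index snapshots (default
#'   `tau / 10`).
#' @param si_shuffles Label shuffles for the in-run randomization null
#'   (default 2000; the final snapshot uses `final_shuffles`).
#' @param final_shuffles Shuffles for the final-state null (default 1e4).
#' @param max_cycles Hard cap on simulated time, in units of `tau`.
#' @param keep_trajectory Keep element snapshots (memory-heavy; default
#'   FALSE keeps only the last).
#' @param progress Print per-snapshot progress.
#' @return List of class `sorting_run`: `si` (data.frame time, n_cells,
#'   XS, mu, sigma, SI), `final_state`, `final` (final-snapshot SI list),
#'   `config`.
#' @export
run_sorting_simulation <- function(config, snapshot_dt = config$tau / 10,
                                   si_shuffles = 2000, final_shuffles = 1e4,
                                   max_cycles = 3, keep_trajectory = FALSE,
                                   progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  state <- init_state(config)
  state <- relax_state(state, duration = 0.05 * config$tau)
  eff <- effective_config(config)
  steps_per_snap <- max(1L, as.integer(round(snapshot_dt / config$dt)))
  chunks_per_snap <- 4L
  steps_per_chunk <- max(1L, steps_per_snap %/% chunks_per_snap)
  si_rows <- list()
  traj <- list()
  settle_left <- NA_real_
  with_seed(config$seed + 777L, {
    repeat {
      for (ch in seq_len(chunks_per_snap)) {
        res <- cpp_sem_advance(state$positions, state$cell_id,
                               as.integer(state$cell_type == "PrE"),
                               state$phase, eff, state$time,
                               steps_per_chunk, config$rebuild_every)
        state$positions <- res$positions
        state$time <- res$time
        state <- grow_and_divide(state, config,
                                 elapsed = steps_per_chunk * config$dt)
      }
      snap <- aggregate_snapshot(state)
      si <- sorting_index_of(snap, n_shuffles = si_shuffles,
                             seed = config$seed + length(si_rows))
      si_rows[[length(si_rows) + 1L]] <-
        data.frame(time = state$time, n_cells = length(state$cell_type),
                   XS = si$XS, mu = si$mu, sigma = si$sigma, SI = si$SI)
      if (keep_trajectory) traj[[length(traj) + 1L]] <- trajectory_frame(state)
      if (progress)
        message(sprintf("t = %.1f  cells = %d  SI = %.2f", state$time,
                        length(state$cell_type), si$SI))
      if (is.na(settle_left) && length(state$cell_type) >= config$n_end)
        settle_left <- config$settle_frac * config$tau
      if (!is.na(settle_left)) {
        settle_left <- settle_left - snapshot_dt
        if (settle_left <= 0) break
      }
      if (state$time >= max_cycles * config$tau) break
    }
  })
  snap <- aggregate_snapshot(state)
  fin <- sorting_index_of(snap, n_shuffles = final_shuffles,
                          seed = config$seed + 10000L)
  out <- list(si = do.call(rbind, si_rows), final_state = state, final = fin,
              config = config)
  if (keep_trajectory) out$trajectory <- traj
  class(out) <- "sorting_run"
  out
}

#' Labeled aggregate snapshot of a simulation state
#'
#' Recomputes cortex flags per cell and wraps the element cloud as a
#' [labeled_aggregate()] for the sorting statistics.
#'
#' @param state An `aggregate_state`.
#' @return A `labeled_aggregate`.
#' @export
aggregate_snapshot <- function(state) {
  n <- nrow(state$positions)
  cortex <- logical(n)
  for (c in seq_along(state$cell_type)) {
    rows <- which(state$cell_id == c)
    cortex[rows] <- identify_cortex_elements(state$positions[rows, , drop = FALSE],
                                             state$config$cone_deg)
  }
  labeled_aggregate(state$positions, state$cell_type,
                    cell_id = state$cell_id, cortex = cortex)
}

# plain data.frame view of element state (trajectory export)
trajectory_frame <- function(state) {
  snap <- aggregate_snapshot(state)
  data.frame(element_id = seq_len(nrow(state$positions)),
             cell_id = state$cell_id,
             cell_type = state$cell_type[state$cell_id],
             x = state$positions[, 1], y = state$positions[, 2],
             z = state$positions[, 3],
             cortex_flag = snap$cortex,
             time = state$time)
}

#' Write a sorting run to disk
#'
#' Per-snapshot SI series as CSV plus a JSON run manifest (config and
#' seed); the final element state as CSV.
#'
#' @param run A `sorting_run`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_sorting_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$si, file.path(dir, "sorting_index.csv"), row.names = FALSE)
  write.csv(trajectory_frame(run$final_state),
            file.path(dir, "final_elements.csv"), row.names = FALSE)
  jsonlite::write_json(list(config = unclass(run$config),
                            final = run$final[c("XS", "mu", "sigma", "SI")]),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# deterministic per-run seed for sweeps (kept below 2^31)
sweep_seed <- function(master, beta, epsilon, replicate) {
  as.integer((master * 2654435761 + round(beta * 100) * 1000003 +
                round(epsilon * 100) * 7919 + replicate * 104729) %% 2147483563) + 1L
}

#' Sweep the affinity-fluctuation phase space
#'
#' Runs [run_sorting_simulation()] over a beta x epsilon grid with
#' replicate averaging, the phase-space protocol (default grid step 0.05).
#'
#' @param beta_values,epsilon_values Grid values.
#' @param replicates Seeded replicates per grid point.
#' @param config Base `sim_config`; its seed acts as the master seed.
#' @param ... Passed to [run_sorting_simulation()].
#' @return Data frame with one row per (beta, epsilon, replicate) and the
#'   final sorting index.
#' @export
sweep_sorting <- function(beta_values, epsilon_values, replicates = 4L,
                          config = sim_config(), ...) {
  rows <- list()
  for (b in beta_values) for (e in epsilon_values) for (r in seq_len(replicates)) {
    cfg <- config
    cfg$beta <- b
    cfg$epsilon <- e
    cfg$seed <- sweep_seed(config$seed, b, e, r)
    cfg <- validate_sim_config(unclass(cfg))
    run <- run_sorting_simulation(cfg, ...)
    rows[[length(rows) + 1L]] <-
      data.frame(beta = b, epsilon = e, replicate = r, seed = cfg$seed,
                 SI_final = run$final$SI, XS_final = run$final$XS,
                 n_cells = length(run$final_state$cell_type))
  }
  do.call(rbind, rows)
}
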