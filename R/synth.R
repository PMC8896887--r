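# Run code under a local, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(as.integer(seed))
  force(code)
}

#' Synthetic membrane movie with known fluctuation amplitude
#'
#' Generates star-convex membrane contours sampled at fixed intervals
#' (default every 10 s over 5 min, i.e. 31 frames), with radius
#' \deqn{\rho(\theta, t) = R_0 + \sum_m a_m \sin(k_m\theta + \psi_m)\sin(2\pi t/T_m + \chi_m)}
#' plus optional Gaussian noise. The analytic temporal fluctuation
#' amplitude of the noise-free signal is stored as ground truth
#' (`vt_true`), evaluated exactly on a fine angular grid, together with the
#' per-mode quadrature contributions.
#'
#' @param R0 Mean radius (micrometres).
#' @param modes Data frame or list of rows `(k, amplitude, period)`:
#'   angular wavenumber (integer >= 1), amplitude (um, < R0/3 for
#'   star-convexity), temporal period (s). Periods should divide the total
#'   duration for the stated closed forms to hold exactly.
#' @param n_frames Frames (default 31).
#' @param frame_interval Seconds between frames (default 10).
#' @param noise_sd Gaussian radial noise SD (um).
#' @param points_per_frame Boundary points per contour.
#' @param seed Mandatory integer seed.
#' @return List with `frames` (list of xy matrices), `ground_truth`
#'   (`vt_true`, `vt_modes`), and the generating parameters.
#' @export
make_membrane_movie <- function(R0 = 7.2, modes = data.frame(k = 3, amplitude = 1, period = 60),
                                n_frames = 31L, frame_interval = 10,
                                noise_sd = 0, points_per_frame = 720L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  modes <- as.data.frame(modes)
  if (nrow(modes) > 0 && any(modes$amplitude >= R0 / 3))
    stop("mode amplitudes must stay below R0/3 to keep contours star-convex")
  with_seed(seed, {
    psi <- if (nrow(modes)) runif(nrow(modes), 0, 2 * pi) else numeric(0)
    chi <- if (nrow(modes)) runif(nrow(modes), 0, 2 * pi) else numeric(0)
    times <- (seq_len(n_frames) - 1L) * frame_interval
    th <- seq(0, 2 * pi, length.out = points_per_frame + 1L)[-1L]
    frames <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      rho <- rep(R0, points_per_frame)
      if (nrow(modes)) for (m in seq_len(nrow(modes))) {
        rho <- rho + modes$amplitude[m] * sin(modes$k[m] * th + psi[m]) *
          sin(2 * pi * times[i] / modes$period[m] + chi[m])
      }
      if (noise_sd > 0) rho <- rho + rnorm(points_per_frame, 0, noise_sd)
      if (any(rho <= 0)) stop("contour collapsed through the origin")
      frames[[i]] <- cbind(rho * cos(th), rho * sin(th))
    }
    # exact noise-free ground truth: per-bin temporal SD on a fine grid.
    # Temporal SD of sin(2 pi t/T + chi) over the sampled frames (population).
    fine <- seq(0, 2 * pi, length.out = 4096L)
    var_bin <- rep(0, length(fine))
    vt_modes <- numeric(nrow(modes))
    if (nrow(modes)) for (m in seq_len(nrow(modes))) {
      s_t <- sin(2 * pi * times / modes$period[m] + chi[m])
      sd_t <- sd_pop(s_t)
      var_bin <- var_bin + (modes$amplitude[m] * sin(modes$k[m] * fine + psi[m]))^2 * sd_t^2
      vt_modes[m] <- modes$amplitude[m] * (2 / pi) * sd_t
    }
    vt_true <- mean(sqrt(var_bin))
    list(frames = frames,
         ground_truth = list(vt_true = vt_true, vt_modes = vt_modes),
         R0 = R0, modes = modes, psi = psi, chi = chi,
         n_frames = n_frames, frame_interval = frame_interval,
         noise_sd = noise_sd, seed = seed)
  })
}

#' Synthetic sphere-packed aggregate with a known arrangement
#'
#' Packs `n_cells` unit-radius cells into a ball by random sequential
#' insertion and labels them `random`ly, as a `core_shell` (PrE occupying
#' the outer radial shell, the sorted configuration), or `inverted` (EPI
#' outside).
#'
#' @param n_cells Number of cells (>= 4).
#' @param arrangement One of `"random"`, `"core_shell"`, `"inverted"`.
#' @param prE_fraction Fraction of PrE cells (default 0.5).
#' @param seed Mandatory integer seed.
#' @return A `labeled_aggregate` with attribute `ground_truth` (the
#'   arrangement and seed).
#' @export
make_aggregate <- function(n_cells, arrangement = c("random", "core_shell", "inverted"),
                           prE_fraction = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  arrangement <- match.arg(arrangement)
  stopifnot(n_cells >= 4L, prE_fraction > 0, prE_fraction < 1)
  with_seed(seed, {
    r_min <- 1.9                      # centre separation for unit-radius cells
    R_agg <- 1.1 * n_cells^(1 / 3)    # ball radius; grown on packing failure
    repeat {
      pos <- matrix(NA_real_, n_cells, 3L)
      k <- 0L; tries <- 0L
      while (k < n_cells && tries < 20000L) {
        p <- runif(3, -1, 1)
        if (sum(p^2) > 1) { tries <- tries + 1L; next }
        p <- p * R_agg
        if (k == 0L || min(sqrt(rowSums(sweep(pos[seq_len(k), , drop = FALSE], 2L, p)^2))) >= r_min) {
          k <- k + 1L
          pos[k, ] <- p
        }
        tries <- tries + 1L
      }
      if (k == n_cells) break
      R_agg <- R_agg * 1.1
    }
    n_pre <- round(prE_fraction * n_cells)
    d <- sqrt(rowSums(sweep(pos, 2L, colMeans(pos))^2))
    types <- rep("EPI", n_cells)
    if (arrangement == "random") {
      types[sample.int(n_cells, n_pre)] <- "PrE"
    } else if (arrangement == "core_shell") {
      types[order(d, decreasing = TRUE)[seq_len(n_pre)]] <- "PrE"
    } else {
      types[order(d, decreasing = FALSE)[seq_len(n_pre)]] <- "PrE"
    }
    agg <- labeled_aggregate(pos, types)
    attr(agg, "ground_truth") <- list(arrangement = arrangement, seed = seed,
                                      prE_fraction = prE_fraction)
    agg
  })
}

#' Synthetic doublet record from imposed tensions
#'
#' Solves the three-tension force balance ([doublet_from_tensions()]) and
#' optionally perturbs the measured angles with Gaussian noise, storing the
#' noise-free affinity-relevant ground truth.
#'
#' @param gamma_1,gamma_2,gamma_12 Tension triple (see
#'   [doublet_from_tensions()]).
#' @param radius Cell-1 radius (um).
#' @param angle_noise_sd SD of angle measurement noise (degrees).
#' @param seed Mandatory integer seed.
#' @return A `doublet_record` with noisy `theta_left/right/theta_e` and a
#'   `ground_truth` attribute carrying the exact angles.
#' @export
make_doublet <- function(gamma_1, gamma_2, gamma_12, radius = 7.2,
                         angle_noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  with_seed(seed, {
    rec <- doublet_from_tensions(gamma_1, gamma_2, gamma_12, radius)
    truth <- list(theta_1 = rec$theta_1, theta_2 = rec$theta_2,
                  waist = rec$waist, seed = seed)
    if (angle_noise_sd > 0) {
      rec$theta_left <- rec$theta_left + rnorm(1, 0, angle_noise_sd)
      rec$theta_right <- rec$theta_right + rnorm(1, 0, angle_noise_sd)
      rec$theta_1 <- mean(c(rec$theta_left, rec$theta_right))
      rec$theta_2 <- rec$theta_2 + mean(rnorm(2, 0, angle_noise_sd))
      rec$theta_e <- mean(c(rec$theta_1, rec$theta_2))
    }
    attr(rec, "ground_truth") <- truth
    rec
  })
}

#' Synthetic parallel-plate compression record
#'
#' Inverts the compression force balance: given a true tension and the
#' compressed geometry, computes the plateau force (plus optional noise)
#' that [afm_tension()] should decode.
#'
#' @param T_true True surface tension (N/m).
#' @param r_mid Mid-section radius (m).
#' @param h_cell Compressed height (m); must leave a positive contact
#'   area.
#' @param noise_sd Relative (fractional) Gaussian noise on the force.
#' @param seed Mandatory integer seed.
#' @return List with `F`, `r_mid`, `A_mid`, `h_cell`, `r_c` and
#'   `ground_truth$T_true`.
#' @export
make_afm_record <- function(T_true, r_mid = 10e-6, h_cell = 10e-6,
                            noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  chk_num(T_true, "T_true", 0)
  with_seed(seed, {
    A_mid <- pi * r_mid^2
    A_c <- afm_contact_area(A_mid, h_cell)
    r_c <- sqrt(A_c / pi)
    F <- T_true * 2 * pi * r_mid / (r_mid^2 / r_c^2 - 1)
    if (noise_sd > 0) F <- F * (1 + rnorm(1, 0, noise_sd))
    list(F = F, r_mid = r_mid, A_mid = A_mid, h_cell = h_cell, r_c = r_c,
         ground_truth = list(T_true = T_true, seed = seed))
  })
}

#' Random binary mixture for self-propelled-Voronoi runs
#'
#' Uniform random cell centres in a periodic square box with 50/50 (or as
#' requested) subtype labels and per-subtype preferred shape indices; the
#' initially mixed condition of the demixing simulations.
#'
#' @param n_cells Number of cells (>= 16).
#' @param p0_pair Preferred shape indices of the two subtypes (default the
#'   solid-like/fluid-like pair `c(3.65, 4.05)`).
#' @param fraction Fraction of subtype 2 (default 0.5; counts differ by at
#'   most one).
#' @param box Box side length; default `sqrt(n_cells)` so mean cell area
#'   is 1.
#' @param seed Mandatory integer seed.
#' @return List with `centers` (n x 2), `subtype` (1/2), `p0` per cell,
#'   `box`, `seed`.
#' @export
make_vertex_mixture <- function(n_cells, p0_pair = c(3.65, 4.05),
                                fraction = 0.5, box = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_cells >= 16L, length(p0_pair) == 2L)
  if (is.null(box)) box <- sqrt(n_cells)
  with_seed(seed, {
    centers <- cbind(runif(n_cells, 0, box), runif(n_cells, 0, box))
    n2 <- round(fraction * n_cells)
    subtype <- rep(1L, n_cells)
    subtype[sample.int(n_cells, n2)] <- 2L
    list(centers = centers, subtype = subtype, p0 = p0_pair[subtype],
         p0_pair = p0_pair, box = box, seed = seed)
  })
}

#' Breathing-ellipse mask stack with a prescribed shape-index CV
#'
#' Renders binary masks of an ellipse whose aspect ratio is modulated over
#' one full period so the analytic shape-index series has the requested
#' mean and coefficient of variation (area held fixed).
#'
#' @param mean_s Target mean shape index (>= 2*sqrt(pi)).
#' @param cv Target temporal CV of the shape index (population SD / mean).
#' @param n_frames Frames (default 15).
#' @param resolution Mask side length in pixels (default 512).
#' @param pixel_size Micrometres per pixel (default 0.2).
#' @param diameter_um Equivalent-circle cell diameter (default 14 um).
#' @param seed Mandatory integer seed (randomizes the phase only).
#' @return List with `masks` (list of logical matrices), `s_true` (the
#'   analytic series), `ground_truth` (`mean_s`, `cv`).
#' @export
make_shape_series <- function(mean_s = 4.0, cv = 0.05, n_frames = 15L,
                              resolution = 512L, pixel_size = 0.2,
                              diameter_um = 14, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (mean_s < 2 * sqrt(pi)) stop("mean_s below the circle bound 2*sqrt(pi)")
  chk_num(cv, "cv", 0)
  b_rel <- sqrt(2) * cv
  t_idx <- (seq_len(n_frames) - 1L) / n_frames
  with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    s_true <- mean_s * (1 + b_rel * sin(2 * pi * t_idx + phase))
    if (any(s_true < 2 * sqrt(pi)))
      stop("requested cv drives the shape index below the circle bound")
    # ellipse with unit area scale: s(q) for semi-axes (q, 1/q), area pi
    s_of_q <- function(q) {
      a <- q; b <- 1 / q
      h <- ((a - b) / (a + b))^2
      P <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
      P / sqrt(pi * a * b)
    }
    q_for_s <- function(s) {
      if (s <= 2 * sqrt(pi) + 1e-12) return(1)
      stats::uniroot(function(q) s_of_q(q) - s, c(1, 20), tol = 1e-10)$root
    }
    q_t <- vapply(s_true, q_for_s, 0)
    area_px <- pi * (diameter_um / 2 / pixel_size)^2
    scale_px <- sqrt(area_px / pi)       # semi-axis scale so area matches
    ctr <- (resolution + 1) / 2
    xs <- seq_len(resolution) - ctr
    masks <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      a <- q_t[i] * scale_px
      b <- scale_px / q_t[i]
      masks[[i]] <- outer(xs, xs, function(x, y) (x / a)^2 + (y / b)^2 <= 1)
    }
    list(masks = masks, s_true = s_true, q = q_t,
         ground_truth = list(mean_s = mean_s, cv = cv, seed = seed),
         pixel_size = pixel_size, resolution = resolution)
  })
}
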