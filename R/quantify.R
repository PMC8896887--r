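#' Resample membrane contours onto a polar grid
#'
#' Converts per-frame membrane boundary points into polar radii
#' \eqn{\rho_j(t_i)} on a uniform angular grid, using the centroid of the
#' first frame as the origin for every frame (the registration convention
#' for single-cell movies). Radii are obtained by linear interpolation of
#' the contour's angle-radius samples; where a frame crosses an angle more
#' than once (a protruding bleb), the outermost crossing is kept.
#'
#' @param frames A list of two-column matrices (x, y), one closed boundary
#'   per frame, in micrometres (apply pixel calibration beforehand) or with
#'   `pixel_size` to convert.
#' @param M Number of uniform angular bins (default 360).
#' @param pixel_size Optional micrometres per pixel; applied to coordinates.
#' @param frame_interval Seconds between frames (metadata, default 10).
#' @return An object of class `contour_stack`: list with `rho` (M x N
#'   matrix, micrometres), `theta` (bin centres, radians), `origin`,
#'   `frame_interval`, `duration`.
#' @export
contour_to_polar <- function(frames, M = 360L, pixel_size = NULL,
                             frame_interval = 10) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  M <- as.integer(M)
  if (M < 16L) stop("need at least 16 angular bins")
  if (!is.null(pixel_size)) frames <- lapply(frames, function(f) f * pixel_size)
  origin <- colMeans(frames[[1L]])
  theta <- (seq_len(M) - 0.5) / M * 2 * pi - pi
  rho <- matrix(NA_real_, M, length(frames))
  warned <- FALSE
  wrap_pi <- function(a) atan2(sin(a), cos(a))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    x <- f[, 1] - origin[1]
    y <- f[, 2] - origin[2]
    ang <- atan2(y, x)
    r <- sqrt(x^2 + y^2)
    if (any(r <= 0)) stop("boundary passes through the origin; invalid contour")
    # walk the contour in its own order; each segment sweeps a small angular
    # interval. Every bin centre inside the interval receives the linearly
    # interpolated radius; where a bin is crossed more than once (a bleb
    # folding back in angle) the outermost crossing wins.
    n <- length(ang)
    nxt <- c(2:n, 1L)
    d <- wrap_pi(ang[nxt] - ang)
    if (any(d > 0) && any(d < 0) && !warned) {
      warning("non-star-convex frame(s): keeping outermost crossing per angle")
      warned <- TRUE
    }
    rho_i <- rep(-Inf, M)
    for (k in seq_len(n)) {
      dk <- d[k]
      if (abs(dk) < 1e-12) next
      a1 <- ang[k]
      # bin centres within the swept interval [a1, a1 + dk]
      off <- wrap_pi(theta - a1)
      if (dk > 0) sel <- which(off >= 0 & off <= dk)
      else sel <- which(off <= 0 & off >= dk)
      if (!length(sel)) next
      tfrac <- off[sel] / dk
      rr <- r[k] + tfrac * (r[nxt[k]] - r[k])
      rho_i[sel] <- pmax(rho_i[sel], rr)
    }
    if (any(!is.finite(rho_i))) {
      # bins not swept (sparse sampling): fall back to nearest-angle value
      miss <- which(!is.finite(rho_i))
      for (m_i in miss) {
        j <- which.min(abs(wrap_pi(ang - theta[m_i])))
        rho_i[m_i] <- r[j]
      }
    }
    rho[, i] <- rho_i
  }
  structure(list(rho = rho, theta = theta, origin = origin,
                 frame_interval = frame_interval,
                 duration = frame_interval * (length(frames) - 1L)),
            class = "contour_stack")
}

#' Detrend a contour stack per frame
#'
#' Subtracts each frame's angular-mean radius so every frame's residual
#' mean is exactly zero. This removes cell size (and its slow changes, e.g.
#' growth or focal-plane drift) before fluctuation amplitudes are computed.
#'
#' @param stack A `contour_stack` (or a bare M x N radius matrix).
#' @return A matrix of residuals with per-frame zero mean.
#' @export
detrend_frames <- function(stack) {
  rho <- if (inherits(stack, "contour_stack")) stack$rho else as.matrix(stack)
  sweep(rho, 2L, colMeans(rho))
}

# population standard deviation (divisor N)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Temporal surface-fluctuation amplitude
#'
#' For each angular bin j the standard deviation over time of the
#' detrended radius is taken; the amplitude is the mean over the M bins:
#' \deqn{V_T = \overline{\mathrm{SD}\{\rho_j(t_1),\ldots,\rho_j(t_N)\}}_{j=1:M}}
#' Population SD is used (configurable).
#'
#' @param residuals Detrended M x N radius matrix (see [detrend_frames()]),
#'   or a `contour_stack` which is detrended first.
#' @param sample_sd Use the sample (N-1) SD instead of population SD.
#' @return V_T in the units of the radii (micrometres).
#' @export
fluctuation_amplitude <- function(residuals, sample_sd = FALSE) {
  if (inherits(residuals, "contour_stack")) residuals <- detrend_frames(residuals)
  residuals <- as.matrix(residuals)
  if (ncol(residuals) < 2L) stop("need at least 2 frames")
  f <- if (sample_sd) stats::sd else sd_pop
  mean(apply(residuals, 1L, f))
}

#' Normalize fluctuation amplitudes by a reference group
#'
#' Divides each value by the mean of the reference group within its
#' stratum (experiment/condition), the convention used to pool amplitudes
#' across time points and conditions with EPI progenitors as reference.
#'
#' @param values Numeric amplitudes.
#' @param is_reference Logical, same length: membership of the reference
#'   group (e.g. EPI).
#' @param stratum Optional factor of experiment/condition strata; each
#'   stratum is normalized independently.
#' @return Values divided by their stratum's reference mean.
#' @export
normalize_fluctuations <- function(values, is_reference, stratum = NULL) {
  stopifnot(length(values) == length(is_reference))
  if (is.null(stratum)) stratum <- rep(1L, length(values))
  out <- numeric(length(values))
  for (s in unique(stratum)) {
    in_s <- stratum == s
    ref <- values[in_s & is_reference]
    if (length(ref) == 0L) stop("empty reference group in stratum ", s)
    m <- mean(ref)
    if (m <= 0) stop("reference-group mean must be positive in stratum ", s)
    out[in_s] <- values[in_s] / m
  }
  out
}

# Sub-pixel boundary of a binary mask via linear iso-contouring at 0.5
# after light smoothing; returns a closed polygon (matrix, pixel units).
mask_contour <- function(mask, smooth_sigma = 1.5) {
  m <- as.matrix(mask) * 1.0
  if (smooth_sigma > 0) {
    k <- ceiling(3 * smooth_sigma)
    g <- stats::dnorm(seq(-k, k), sd = smooth_sigma)
    g <- g / sum(g)
    pad <- function(v, n) c(rep(v[1], n), v, rep(v[length(v)], n))
    smooth1 <- function(v) stats::filter(pad(v, k), g, sides = 2)[(k + 1):(k + length(v))]
    m <- apply(m, 2L, smooth1)
    m <- t(apply(m, 1L, smooth1))
  }
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m, levels = 0.5)
  if (length(cl) == 0L) stop("empty mask: no boundary found")
  if (length(cl) > 1L) {
    # keep the longest contour (single-component requirement checked upstream)
    len <- vapply(cl, function(cc) length(cc$x), 0L)
    cl <- cl[which.max(len)]
  }
  cbind(cl[[1]]$x, cl[[1]]$y)
}

polygon_perimeter <- function(poly) {
  d <- diff(rbind(poly, poly[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# count connected components (4-connectivity) of a binary mask
n_components <- function(mask) {
  m <- as.matrix(mask) > 0
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        a <- p[1]; b <- p[2]
        if (a < 1 || b < 1 || a > nrow(m) || b > ncol(m)) next
        if (!m[a, b] || lab[a, b] != 0L) next
        lab[a, b] <- cur
        stack <- c(stack, list(c(a - 1, b), c(a + 1, b), c(a, b - 1), c(a, b + 1)))
      }
    }
  }
  cur
}

#' Shape-index time series from a mask stack
#'
#' Perimeter is measured on the sub-pixel iso-contour of each binary mask
#' (linear marching-squares with light pre-smoothing; pixel-edge counting
#' would overestimate P on disks by tens of percent), area as pixel count
#' times `pixel_size^2`. The shape index is `P/sqrt(A)`, unit-free.
#'
#' @param masks A list of binary matrices (one connected cell per frame),
#'   or a 3D array with frames along the third dimension.
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval Seconds between frames (metadata, default 30).
#' @param check_components Verify single-component masks (slow on large
#'   masks; disable for trusted synthetic input).
#' @return A data.frame of class `shape_series` with columns `frame`,
#'   `perimeter` (um), `area` (um^2), `shape_index`.
#' @export
shape_series_from_masks <- function(masks, pixel_size = 1,
                                    frame_interval = 30,
                                    check_components = FALSE) {
  if (is.array(masks) && length(dim(masks)) == 3L)
    masks <- lapply(seq_len(dim(masks)[3]), function(i) masks[, , i])
  stopifnot(is.list(masks), length(masks) >= 1L)
  out <- data.frame(frame = seq_along(masks), perimeter = NA_real_,
                    area = NA_real_, shape_index = NA_real_)
  for (i in seq_along(masks)) {
    m <- as.matrix(masks[[i]]) > 0
    if (!any(m)) stop("frame ", i, ": empty mask")
    if (check_components && n_components(m) != 1L)
      stop("frame ", i, ": mask must have exactly one connected component")
    poly <- mask_contour(m)
    P <- polygon_perimeter(poly) * pixel_size
    A <- sum(m) * pixel_size^2
    out$perimeter[i] <- P
    out$area[i] <- A
    out$shape_index[i] <- P / sqrt(A)
  }
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("shape_series", "data.frame")
  out
}

#' Temporal coefficient of variation
#'
#' SD over mean of a series (population SD by default); used on shape-index
#' time series as a proxy for cell-shape fluctuations in the tissue bulk.
#'
#' @param series Numeric vector, or a `shape_series` whose `shape_index`
#'   column is used.
#' @param sample_sd Use sample SD instead of population SD.
#' @return The coefficient of variation.
#' @export
cv_over_time <- function(series, sample_sd = FALSE) {
  if (inherits(series, "shape_series")) series <- series$shape_index
  series <- as.numeric(series)
  if (length(series) < 2L) stop("need at least 2 samples")
  m <- mean(series)
  if (m <= 0) stop("mean must be positive for a coefficient of variation")
  (if (sample_sd) stats::sd(series) else sd_pop(series)) / m
}

#' Coefficient of variation of intensity along a cell boundary
#'
#' Samples an intensity image in a band around a closed contour, averages
#' within angular bins about the contour centroid, and returns the SD/mean
#' across bins — a measure of spatial heterogeneity of a cortical signal
#' (e.g. phosphorylated ERM) along the cell surface.
#'
#' @param contour Two-column matrix of boundary points (pixel coordinates).
#' @param image Intensity matrix (row = x, col = y to match the contour).
#' @param band_width Band thickness in pixels, centred on the contour.
#' @param n_bins Angular bins (default 72).
#' @param samples_per_bin Radial samples across the band per boundary point.
#' @return The coefficient of variation across angular bins.
#' @export
boundary_intensity_cov <- function(contour, image, band_width = 3,
                                   n_bins = 72L, samples_per_bin = 5L) {
  stopifnot(is.matrix(contour), ncol(contour) == 2L)
  img <- as.matrix(image)
  centre <- colMeans(contour)
  ang <- atan2(contour[, 2] - centre[2], contour[, 1] - centre[1])
  bin <- pmin(n_bins, pmax(1L, floor((ang + pi) / (2 * pi) * n_bins) + 1L))
  offs <- seq(-band_width / 2, band_width / 2, length.out = samples_per_bin)
  bilin <- function(x, y) {
    x <- pmin(pmax(x, 1), nrow(img)); y <- pmin(pmax(y, 1), ncol(img))
    x0 <- pmin(floor(x), nrow(img) - 1L); y0 <- pmin(floor(y), ncol(img) - 1L)
    fx <- x - x0; fy <- y - y0
    img[cbind(x0, y0)] * (1 - fx) * (1 - fy) + img[cbind(x0 + 1, y0)] * fx * (1 - fy) +
      img[cbind(x0, y0 + 1)] * (1 - fx) * fy + img[cbind(x0 + 1, y0 + 1)] * fx * fy
  }
  clipped <- FALSE
  vals <- numeric(0); vbin <- integer(0)
  for (o in offs) {
    rad <- cbind(cos(ang), sin(ang))
    px <- contour[, 1] + o * rad[, 1]
    py <- contour[, 2] + o * rad[, 2]
    if (any(px < 1 | px > nrow(img) | py < 1 | py > ncol(img))) clipped <- TRUE
    vals <- c(vals, bilin(px, py))
    vbin <- c(vbin, bin)
  }
  if (clipped) warning("sampling band exits the image; clipped to image border")
  bin_means <- tapply(vals, vbin, mean)
  m <- mean(bin_means)
  if (m <= 0) stop("non-positive mean boundary intensity")
  sd_pop(as.numeric(bin_means)) / m
}

#' Fluctuation differential between two lineages
#'
#' The dimensionless excess of PrE over EPI surface-fluctuation amplitude,
#' \eqn{\varepsilon = \delta_{PrE}/\delta_{EPI} - 1}; 0 means equal
#' fluctuations. With the measured amplitudes 1.39 um (EPI) and 1.91 um
#' (PrE) this gives 0.374 (commonly quoted rounded as ~0.35).
#'
#' @param delta_epi EPI fluctuation amplitude (> 0, micrometres).
#' @param delta_pre PrE fluctuation amplitude (same units).
#' @return The dimensionless differential.
#' @export
epsilon_estimate <- function(delta_epi, delta_pre) {
  chk_num(delta_epi, "delta_epi", 0, strict_lower = TRUE)
  chk_num(delta_pre, "delta_pre", 0)
  delta_pre / delta_epi - 1
}
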