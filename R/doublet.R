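#' Cell-cell affinity parameter from homotypic contact angles
#'
#' The affinity parameter \eqn{\beta} compares the cell-cell affinity of two
#' homotypic doublet types through their external contact angles:
#' \eqn{\beta = \cos\theta_a / \cos\theta_b}. For EPI/PrE progenitors,
#' \eqn{\theta_a} is the EPI::EPI and \eqn{\theta_b} the PrE::PrE external
#' contact angle; \eqn{\beta < 1} means EPI-homotypic contacts are
#' energetically favoured, biasing PrE to the aggregate exterior.
#'
#' @param theta_a,theta_b External contact angles in degrees, each in
#'   (0, 90). For the embryonic lineages these are the EPI::EPI and
#'   PrE::PrE angles respectively.
#' @return The dimensionless affinity ratio.
#' @examples
#' affinity_parameter(60, 50.72) # ~0.79
#' @export
affinity_parameter <- function(theta_a, theta_b) {
  for (th in list(a = theta_a, b = theta_b)) {
    if (!is.numeric(th) || any(!is.finite(th)) || any(th <= 0) || any(th >= 90))
      stop("contact angles must lie strictly between 0 and 90 degrees")
  }
  cos(theta_a * pi / 180) / cos(theta_b * pi / 180)
}

#' Construct a doublet geometry from a three-tension force balance
#'
#' Two adhered cells meet at a flat contact disc; at the contact line the
#' interfacial tension \eqn{\gamma_{12}} balances the two cell-medium surface
#' tensions \eqn{\gamma_1, \gamma_2}:
#' \deqn{\gamma_{12} = \gamma_1\cos\theta_1 + \gamma_2\cos\theta_2, \qquad
#'       \gamma_1\sin\theta_1 = \gamma_2\sin\theta_2.}
#' The solution is the tension triangle: \eqn{\cos\theta_1 =
#' (\gamma_1^2 + \gamma_{12}^2 - \gamma_2^2) / (2\gamma_1\gamma_{12})}.
#' The cell with the higher surface tension subtends the smaller external
#' angle. The returned record describes the mid-plane geometry of two
#' spherical caps with those angles.
#'
#' @param gamma_1,gamma_2 Cell-medium surface tensions of the two cells
#'   (arbitrary common units, > 0).
#' @param gamma_12 Interfacial tension at the cell-cell contact (> 0); the
#'   three tensions must satisfy the triangle inequality for a physical
#'   contact with both angles in (0, 90) degrees.
#' @param radius Radius of cell 1 before contact (micrometres); cell 2 is
#'   scaled so both caps share the same contact chord.
#' @return A list of class `doublet_record` with elements `theta_left`,
#'   `theta_right` (degrees; sides of the mid-plane section, equal here by
#'   construction for each cell), `theta_1`, `theta_2`, `theta_e` (their
#'   mean), `waist` (contact chord length, micrometres), `radius_1`,
#'   `radius_2`, and the generating tensions.
#' @export
doublet_from_tensions <- function(gamma_1, gamma_2, gamma_12, radius = 7.2) {
  chk_num(gamma_1, "gamma_1", 0, strict_lower = TRUE)
  chk_num(gamma_2, "gamma_2", 0, strict_lower = TRUE)
  chk_num(gamma_12, "gamma_12", 0, strict_lower = TRUE)
  chk_num(radius, "radius", 0, strict_lower = TRUE)
  c1 <- (gamma_1^2 + gamma_12^2 - gamma_2^2) / (2 * gamma_1 * gamma_12)
  c2 <- (gamma_2^2 + gamma_12^2 - gamma_1^2) / (2 * gamma_2 * gamma_12)
  if (c1 <= 0 || c1 >= 1 || c2 <= 0 || c2 >= 1)
    stop("tensions admit no physical doublet: need both contact angles in (0, 90) degrees")
  th1 <- acos(c1)
  th2 <- acos(c2)
  # Both caps share the contact chord: R_i * sin(theta_i) = half-waist.
  # Scale cell 2 radius so the force-balance angles are realized with a
  # common chord, keeping cell 1 at the requested radius.
  r1 <- radius
  half_chord <- r1 * sin(th1)
  r2 <- half_chord / sin(th2)
  structure(list(
    theta_left  = th1 * 180 / pi,
    theta_right = th1 * 180 / pi,
    theta_1 = th1 * 180 / pi,
    theta_2 = th2 * 180 / pi,
    theta_e = (th1 + th2) / 2 * 180 / pi,
    waist = 2 * half_chord,
    radius_1 = r1, radius_2 = r2,
    gamma_1 = gamma_1, gamma_2 = gamma_2, gamma_12 = gamma_12
  ), class = "doublet_record")
}

#' Mid-plane contour of a doublet record
#'
#' Renders the two truncated-circle (spherical-cap mid-section) outlines of
#' a doublet as polygons, cell 1 on the left of the vertical contact line at
#' x = 0.
#'
#' @param doublet A `doublet_record` from [doublet_from_tensions()].
#' @param n_points Points per cell outline.
#' @return A list with `cell1`, `cell2` (two-column matrices of boundary
#'   points, open arcs from one contact endpoint to the other) and
#'   `contact` (the two contact-line endpoints).
#' @export
doublet_contour <- function(doublet, n_points = 400L) {
  stopifnot(inherits(doublet, "doublet_record"))
  th1 <- doublet$theta_1 * pi / 180
  th2 <- doublet$theta_2 * pi / 180
  r1 <- doublet$radius_1
  r2 <- doublet$radius_2
  c_half <- doublet$waist / 2
  d1 <- r1 * cos(th1)   # centre distance of cell 1 to the contact line
  d2 <- r2 * cos(th2)
  # Cell 1 centre at (-d1, 0): keep the arc on the far side of the chord.
  a1 <- atan2(c_half, d1)            # angular half-extent of the chord
  ang1 <- seq(a1, 2 * pi - a1, length.out = n_points)
  cell1 <- cbind(-d1 + r1 * cos(ang1), r1 * sin(ang1))
  a2 <- atan2(c_half, d2)
  ang2 <- seq(pi - a2, -(pi - a2), length.out = n_points)
  cell2 <- cbind(d2 + r2 * cos(ang2), r2 * sin(ang2))
  list(cell1 = cell1, cell2 = cell2,
       contact = rbind(c(0, c_half), c(0, -c_half)))
}

# Algebraic (Kasa) circle fit; returns c(xc, yc, r).
fit_circle <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  c(sol[1], sol[2], sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

#' Measure the external contact angle of a doublet mid-plane contour
#'
#' Identifies the contact line between the two cell outlines, fits a circle
#' to the free (cell-medium) boundary of each cell near each contact
#' endpoint, and measures the angle between the cell-medium tangent and the
#' contact line. The reported `theta_e` per cell is the mean of the two
#' sides, matching the measurement convention used on mid-section images.
#'
#' @param contour A list with `cell1` and `cell2` boundary point matrices,
#'   as produced by [doublet_contour()] (any rigid transform of it is fine).
#' @param contact_tol Distance below which boundary points of the two cells
#'   are considered in contact, as a fraction of the mean cell radius.
#' @return A list with per-cell angles (`theta_1`, `theta_2`, degrees),
#'   their per-side values, `theta_e` (mean over both cells and sides),
#'   and `waist` (contact segment length).
#' @export
external_contact_angle <- function(contour, contact_tol = 0.02) {
  p1 <- contour$cell1
  p2 <- contour$cell2
  if (is.null(p1) || is.null(p2)) stop("contour must contain 'cell1' and 'cell2'")
  scale_len <- mean(c(
    sqrt(sum(apply(p1, 2, function(v) diff(range(v)))^2)),
    sqrt(sum(apply(p2, 2, function(v) diff(range(v)))^2))
  )) / 2
  # Contact endpoints: the two ends of each open arc (arcs terminate at the
  # contact line). If arcs are closed polygons, fall back to mutual
  # proximity detection.
  ends1 <- rbind(p1[1, ], p1[nrow(p1), ])
  ends2 <- rbind(p2[1, ], p2[nrow(p2), ])
  dmat <- as.matrix(dist(rbind(ends1, ends2)))[1:2, 3:4]
  if (max(apply(dmat, 1, min)) > contact_tol * scale_len)
    stop("no cell-cell contact detected between the two outlines")
  contact_pts <- ends1
  waist <- sqrt(sum((contact_pts[1, ] - contact_pts[2, ])^2))
  if (waist < contact_tol * scale_len)
    stop("no cell-cell contact detected: contact segment has zero length")
  # Contact line direction (unit).
  u <- (contact_pts[2, ] - contact_pts[1, ]) / waist
  angle_for <- function(pts, endpoint_row, k = max(8L, nrow(pts) %/% 10L)) {
    # Fit a circle to the free boundary adjacent to the contact endpoint.
    idx <- if (endpoint_row == 1L) seq_len(min(k, nrow(pts))) else
      seq(nrow(pts) - min(k, nrow(pts)) + 1L, nrow(pts))
    fit <- fit_circle(pts[idx, , drop = FALSE])
    centre <- fit[1:2]; r <- fit[3]
    p0 <- pts[if (endpoint_row == 1L) 1L else nrow(pts), ]
    radial <- (p0 - centre) / sqrt(sum((p0 - centre)^2))
    # Tangent is perpendicular to the radial direction; the external contact
    # angle is between tangent and contact line: cos(theta) = |radial . u_perp|
    # equivalently sin of angle between radial and contact line.
    cos_theta <- abs(sum(radial * c(-u[2], u[1])))
    acos(pmin(1, pmax(-1, cos_theta))) * 180 / pi
  }
  t1a <- angle_for(p1, 1L); t1b <- angle_for(p1, nrow(p1))
  t2a <- angle_for(p2, 1L); t2b <- angle_for(p2, nrow(p2))
  list(theta_1 = mean(c(t1a, t1b)), theta_2 = mean(c(t2a, t2b)),
       theta_1_sides = c(t1a, t1b), theta_2_sides = c(t2a, t2b),
       theta_e = mean(c(t1a, t1b, t2a, t2b)), waist = waist)
}

#' Normalized cell-cell contact size of a doublet
#'
#' Contact (waist) length in the mid-plane divided by the mean cell
#' diameter: 0 for just-touching cells, 1 when the contact spans a full
#' equator of equal fused cells.
#'
#' @param doublet A `doublet_record`, or a list with `waist`, `radius_1`
#'   and `radius_2` entries.
#' @return Dimensionless normalized contact size.
#' @export
normalized_contact_size <- function(doublet) {
  w <- doublet$waist
  r1 <- doublet$radius_1
  r2 <- doublet$radius_2
  if (is.null(w) || is.null(r1) || is.null(r2)) stop("doublet must carry waist and radii")
  w / (r1 + r2)
}
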