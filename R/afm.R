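#' Cell-cantilever contact area in parallel-plate compression
#'
#' For a cell compressed between a dish and a tipless cantilever, the
#' contact area is obtained from the maximum cross-sectional area and the
#' compressed cell height: \eqn{A_c = A_{mid} - (\pi/4) h_{cell}^2}.
#'
#' @param A_mid Maximum cross-sectional area of the compressed cell (m^2,
#'   or any area unit used consistently).
#' @param h_cell Compressed cell height (same length unit as `A_mid`).
#' @return Contact area in the units of `A_mid`.
#' @export
afm_contact_area <- function(A_mid, h_cell) {
  chk_num(A_mid, "A_mid", 0, strict_lower = TRUE)
  chk_num(h_cell, "h_cell", 0)
  A_c <- A_mid - (pi / 4) * h_cell^2
  if (A_c <= 0)
    stop("inconsistent geometry: A_mid - (pi/4) h_cell^2 must be positive")
  A_c
}

#' Cortical tension from parallel-plate compression
#'
#' Force balance for a cell compressed at constant height between two
#' plates, neglecting cantilever tilt and adhesion:
#' \deqn{T = \frac{F}{2\pi r_{mid}} \left(\frac{r_{mid}^2}{r_c^2} - 1\right)^{-1}}
#' is solved here in the equivalent form
#' \eqn{T = F (r_{mid}^2/r_c^2 - 1) / (2\pi r_{mid})} with the plateau force
#' F after stress relaxation.
#'
#' @param F Plateau force exerted by the cell on the cantilever (N).
#' @param r_mid Radius of the maximum cross-section (m).
#' @param r_c Radius of the cell-cantilever contact (m), with
#'   `0 < r_c < r_mid`.
#' @return Surface tension T (N/m).
#' @examples
#' afm_tension(10e-9, 10e-6, 5e-6) # 4.77e-4 N/m
#' @export
afm_tension <- function(F, r_mid, r_c) {
  chk_num(F, "F", 0)
  chk_num(r_mid, "r_mid", 0, strict_lower = TRUE)
  chk_num(r_c, "r_c", 0, strict_lower = TRUE)
  if (r_c >= r_mid) stop("contact radius r_c must be smaller than r_mid")
  F * (r_mid^2 / r_c^2 - 1) / (2 * pi * r_mid)
}

#' Batch AFM tension with optional boxplot outlier filter
#'
#' Applies [afm_tension()] to a table of compression records, deriving the
#' contact radius from [afm_contact_area()] when `r_c` is not given.
#' Ill-shaped cells can yield abnormally high tensions; the optional filter
#' removes values outside the 1.5-IQR boxplot whiskers.
#'
#' @param records Data frame with columns `F`, `r_mid` and either `r_c` or
#'   (`A_mid`, `h_cell`). SI units throughout.
#' @param iqr_filter If `TRUE`, drop tensions outside
#'   `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.
#' @return The input with added columns `r_c` (if derived), `tension`, and
#'   logical `kept`.
#' @export
afm_tension_batch <- function(records, iqr_filter = FALSE) {
  stopifnot(is.data.frame(records), all(c("F", "r_mid") %in% names(records)))
  if (!"r_c" %in% names(records)) {
    if (!all(c("A_mid", "h_cell") %in% names(records)))
      stop("records need either 'r_c' or both 'A_mid' and 'h_cell'")
    records$r_c <- vapply(seq_len(nrow(records)), function(i)
      sqrt(afm_contact_area(records$A_mid[i], records$h_cell[i]) / pi), 0)
  }
  records$tension <- vapply(seq_len(nrow(records)), function(i)
    afm_tension(records$F[i], records$r_mid[i], records$r_c[i]), 0)
  records$kept <- TRUE
  if (iqr_filter && nrow(records) >= 4L) {
    q <- stats::quantile(records$tension, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    records$kept <- records$tension >= q[1] - 1.5 * iqr &
      records$tension <= q[2] + 1.5 * iqr
  }
  records
}
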