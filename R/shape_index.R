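#' Cell shape index
#'
#' Dimensionless elongation measures: in 2D the perimeter divided by the
#' square root of the area, \eqn{s = P/\sqrt{A}} (a circle gives
#' \eqn{2\sqrt{\pi} \approx 3.54}, the isoperimetric minimum); in 3D the
#' surface area over volume to the two-thirds,
#' \eqn{s_3 = S/V^{2/3}} (a sphere gives \eqn{\approx 4.84}, a unit cube 6).
#' Larger values indicate more elongated, more fluid-like cells in
#' vertex-model tissues.
#'
#' @param P Perimeter(s), > 0.
#' @param A Area(s), > 0.
#' @return The shape index (vectorized).
#' @examples
#' shape_index_2d(2 * pi, pi)  # circle: ~3.5449
#' shape_index_2d(4, 1)        # unit square: 4
#' @export
shape_index_2d <- function(P, A) {
  if (!is.numeric(P) || !is.numeric(A) || any(!is.finite(P)) || any(!is.finite(A)))
    stop("P and A must be finite numerics")
  if (any(P <= 0) || any(A <= 0)) stop("P and A must be positive")
  P / sqrt(A)
}

#' @rdname shape_index_2d
#' @param S Surface area(s), > 0.
#' @param V Volume(s), > 0.
#' @export
shape_index_3d <- function(S, V) {
  if (!is.numeric(S) || !is.numeric(V) || any(!is.finite(S)) || any(!is.finite(V)))
    stop("S and V must be finite numerics")
  if (any(S <= 0) || any(V <= 0)) stop("S and V must be positive")
  S / V^(2 / 3)
}
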