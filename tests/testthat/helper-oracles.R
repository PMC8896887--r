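# Brute-force Delaunay edge oracle: an edge belongs to the triangulation
# iff it is part of some 4-point subset with an empty circumsphere.
brute_delaunay_edges <- function(p, tol = 1e-9) {
  n <- nrow(p)
  E <- matrix(0L, 0, 2)
  cmb <- combn(n, 4)
  for (k in seq_len(ncol(cmb))) {
    v <- cmb[, k]
    A <- 2 * sweep(p[v[-1], , drop = FALSE], 2, p[v[1], ])
    b <- rowSums(p[v[-1], , drop = FALSE]^2) - sum(p[v[1], ]^2)
    ctr <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(ctr)) next
    r2 <- sum((ctr - p[v[1], ])^2)
    d2 <- rowSums(sweep(p, 2, ctr)^2)
    if (all(d2[-v] > r2 * (1 + tol))) E <- rbind(E, t(combn(v, 2)))
  }
  out <- unique(t(apply(E, 1, sort)))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

sorted_edges <- function(e) {
  e <- unname(as.matrix(e))
  e <- t(apply(e, 1, sort))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# uniformly random points in the unit ball
runif_ball <- function(n, radius = 1) {
  out <- matrix(NA_real_, n, 3)
  k <- 0L
  while (k < n) {
    p <- runif(3, -1, 1)
    if (sum(p^2) <= 1) { k <- k + 1L; out[k, ] <- p * radius }
  }
  out
}
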