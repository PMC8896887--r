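#' Build a periodic 2D vertex mesh from a Voronoi tessellation
#'
#' Tessellates the given cell centres in a periodic square box (via a
#' tiled Dirichlet tessellation) and assembles the confluent polygonal
#' tiling as a vertex mesh: shared vertices, per-cell counter-clockwise
#' vertex cycles, and per-cell target geometry.
#'
#' @param centers n x 2 matrix of cell centres in `[0, box)^2`.
#' @param box Box side length.
#' @param A0,P0 Preferred areas and perimeters (recycled); defaults `A0 =
#'   box^2 / n` and `P0 = p0 * sqrt(A0)`.
#' @param p0 Preferred shape index used when `P0` is missing (recycled;
#'   default 3.8).
#' @param KA,KP Area and perimeter moduli (recycled, default 1).
#' @param subtype Optional per-cell subtype labels carried through.
#' @return A list of class `vertex_mesh`: `vertices` (V x 2), `cells`
#'   (list of vertex-index cycles), `offsets` (list of cycle periodic
#'   offsets, same shapes), `A0`, `P0`, `KA`, `KP`, `subtype`, `box`.
#' @export
build_vertex_mesh <- function(centers, box, A0 = NULL, P0 = NULL, p0 = 3.8,
                              KA = 1, KP = 1, subtype = NULL) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (is.null(A0)) A0 <- box^2 / n
  A0 <- rep_len(A0, n); KA <- rep_len(KA, n); KP <- rep_len(KP, n)
  if (is.null(P0)) P0 <- rep_len(p0, n) * sqrt(A0)
  P0 <- rep_len(P0, n)
  # 3x3 tiling for periodicity
  offs <- expand.grid(ox = -1:1, oy = -1:1)
  tiled <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
    cbind(centers[, 1] + offs$ox[k] * box, centers[, 2] + offs$oy[k] * box)))
  dd <- deldir::deldir(tiled[, 1], tiled[, 2],
                       rw = c(-box, 2 * box, -box, 2 * box), suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)
  base_idx <- which(offs$ox == 0 & offs$oy == 0)  # row block of central copy
  base_rows <- (base_idx - 1L) * n + seq_len(n)
  # merge shared vertices by rounded coordinates (wrapped into the box)
  key_of <- function(x, y) paste(round(x / box * 1e8), round(y / box * 1e8))
  vmap <- new.env(hash = TRUE)
  verts <- list()
  cells <- vector("list", n)
  offsets <- vector("list", n)
  for (i in seq_len(n)) {
    t_i <- tl[[base_rows[i]]]
    vx <- t_i$x; vy <- t_i$y
    wx <- vx - box * floor(vx / box)
    wy <- vy - box * floor(vy / box)
    ids <- integer(length(vx))
    off <- matrix(0, length(vx), 2)
    for (k in seq_along(vx)) {
      key <- key_of(wx[k], wy[k])
      id <- vmap[[key]]
      if (is.null(id)) {
        verts[[length(verts) + 1L]] <- c(wx[k], wy[k])
        id <- length(verts)
        vmap[[key]] <- id
      }
      ids[k] <- id
      off[k, ] <- c(floor(vx[k] / box), floor(vy[k] / box))
    }
    cells[[i]] <- ids
    offsets[[i]] <- off
  }
  V <- do.call(rbind, verts)
  mesh <- list(vertices = V, cells = cells, offsets = offsets,
               A0 = A0, P0 = P0, KA = KA, KP = KP,
               subtype = subtype, box = box)
  class(mesh) <- "vertex_mesh"
  refresh_offsets(mesh)
}

# Recompute each cycle's periodic offsets by minimum-image walking from its
# first vertex (keeps geometry consistent as vertices move or swap).
refresh_offsets <- function(mesh) {
  V <- mesh$vertices
  box <- mesh$box
  for (i in seq_along(mesh$cells)) {
    ids <- mesh$cells[[i]]
    off <- matrix(0, length(ids), 2)
    for (k in seq_along(ids)[-1]) {
      prev <- V[ids[k - 1L], ] + off[k - 1L, ] * box
      off[k, ] <- round((prev - V[ids[k], ]) / box)
    }
    mesh$offsets[[i]] <- off
  }
  mesh
}

# unwrapped polygon coordinates of cell i
cell_polygon <- function(mesh, i) {
  mesh$vertices[mesh$cells[[i]], , drop = FALSE] + mesh$offsets[[i]] * mesh$box
}

#' Per-cell areas and perimeters of a vertex mesh
#'
#' @param mesh A `vertex_mesh`.
#' @return Data frame with `area`, `perimeter`, `shape_index` per cell.
#' @export
mesh_geometry <- function(mesh) {
  n <- length(mesh$cells)
  A <- numeric(n); P <- numeric(n)
  for (i in seq_len(n)) {
    poly <- cell_polygon(mesh, i)
    A[i] <- polygon_area(poly)
    P[i] <- polygon_perimeter(poly)
  }
  data.frame(area = A, perimeter = P, shape_index = P / sqrt(A))
}

#' Vertex-model tissue energy
#'
#' The standard confluent-tissue energy
#' \deqn{E = \sum_c K_A (A_c - A_{0,c})^2 + K_P (P_c - P_{0,c})^2.}
#'
#' @param mesh A `vertex_mesh`.
#' @return The scalar energy.
#' @export
tissue_energy <- function(mesh) {
  g <- mesh_geometry(mesh)
  sum(mesh$KA * (g$area - mesh$A0)^2 + mesh$KP * (g$perimeter - mesh$P0)^2)
}

#' Energy gradient with respect to vertex positions
#'
#' Analytic derivative of [tissue_energy()]; the force on a vertex is the
#' negative gradient.
#'
#' @param mesh A `vertex_mesh`.
#' @return V x 2 gradient matrix.
#' @export
tissue_gradient <- function(mesh) {
  V <- mesh$vertices
  G <- matrix(0, nrow(V), 2L)
  for (i in seq_along(mesh$cells)) {
    poly <- cell_polygon(mesh, i)
    m <- nrow(poly)
    A <- polygon_area(poly)
    P <- polygon_perimeter(poly)
    # signed area for orientation of the area derivative
    x <- poly[, 1]; y <- poly[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    sgn <- if (sum(x * yn - xn * y) >= 0) 1 else -1
    cA <- 2 * mesh$KA[i] * (A - mesh$A0[i])
    cP <- 2 * mesh$KP[i] * (P - mesh$P0[i])
    nxt <- c(2:m, 1L); prv <- c(m, 1:(m - 1L))
    dA <- 0.5 * sgn * cbind(poly[nxt, 2] - poly[prv, 2],
                            poly[prv, 1] - poly[nxt, 1])
    dprev <- poly - poly[prv, , drop = FALSE]
    dnext <- poly - poly[nxt, , drop = FALSE]
    lp <- sqrt(rowSums(dprev^2)); ln <- sqrt(rowSums(dnext^2))
    dP <- dprev / pmax(lp, 1e-14) + dnext / pmax(ln, 1e-14)
    contrib <- cA * dA + cP * dP
    ids <- mesh$cells[[i]]
    for (k in seq_len(m)) G[ids[k], ] <- G[ids[k], ] + contrib[k, ]
  }
  G
}

#' Edge list of a vertex mesh
#'
#' @param mesh A `vertex_mesh`.
#' @return Data frame with vertex pair (`v1 < v2`) and the one or two
#'   adjacent cells (`cell_a`, `cell_b`; `NA` if unshared).
#' @export
mesh_edges <- function(mesh) {
  acc <- new.env(hash = TRUE)
  for (i in seq_along(mesh$cells)) {
    ids <- mesh$cells[[i]]
    m <- length(ids)
    for (k in seq_len(m)) {
      a <- ids[k]; b <- ids[if (k == m) 1L else k + 1L]
      key <- paste(min(a, b), max(a, b))
      cur <- acc[[key]]
      if (is.null(cur)) acc[[key]] <- c(min(a, b), max(a, b), i, NA)
      else { cur[4] <- i; acc[[key]] <- cur }
    }
  }
  rows <- do.call(rbind, as.list(acc))
  df <- data.frame(v1 = rows[, 1], v2 = rows[, 2],
                   cell_a = rows[, 3], cell_b = rows[, 4])
  df[order(df$v1, df$v2), , drop = FALSE]
}

#' Line tension of a mesh edge
#'
#' Derivative of the tissue energy with respect to the edge length at
#' fixed topology: \eqn{\Lambda = \sum_{c \ni e} 2 K_P (P_c - P_{0,c})}.
#' Positive values are contractile, negative extensile.
#'
#' @param mesh A `vertex_mesh`.
#' @param edges Optional data frame from [mesh_edges()] (recomputed if
#'   missing).
#' @return The `edges` data frame with a `tension` column (and `length`).
#' @export
edge_tension <- function(mesh, edges = NULL) {
  if (is.null(edges)) edges <- mesh_edges(mesh)
  g <- mesh_geometry(mesh)
  dev <- 2 * mesh$KP * (g$perimeter - mesh$P0)
  t_a <- dev[edges$cell_a]
  t_b <- ifelse(is.na(edges$cell_b), 0, dev[ifelse(is.na(edges$cell_b), 1L, edges$cell_b)])
  edges$tension <- t_a + t_b
  d <- mesh$vertices[edges$v1, , drop = FALSE] - mesh$vertices[edges$v2, , drop = FALSE]
  d <- d - round(d / mesh$box) * mesh$box
  edges$length <- sqrt(rowSums(d^2))
  edges
}

# --- T1 topology change ---------------------------------------------------

# try a T1 swap on edge (a, b); returns updated mesh or NULL if the local
# configuration is not a standard 4-cell junction.
t1_swap <- function(mesh, a, b, l_new) {
  has_a <- vapply(mesh$cells, function(ids) a %in% ids, TRUE)
  has_b <- vapply(mesh$cells, function(ids) b %in% ids, TRUE)
  PQ <- which(has_a & has_b)
  Ronly <- which(has_a & !has_b)
  Sonly <- which(!has_a & has_b)
  if (length(PQ) != 2L || length(Ronly) != 1L || length(Sonly) != 1L) return(NULL)
  P <- PQ[1]; Q <- PQ[2]; R <- Ronly; S <- Sonly
  V <- mesh$vertices; box <- mesh$box
  minimg <- function(d) d - round(d / box) * box
  mid <- V[a, ] + minimg(V[b, ] - V[a, ]) / 2
  ed <- minimg(V[b, ] - V[a, ])
  en <- c(-ed[2], ed[1])
  en <- en / sqrt(sum(en^2))
  ctr <- function(i) {
    poly <- cell_polygon(mesh, i)
    cm <- colMeans(poly)
    mid + minimg(cm - mid)
  }
  # new edge points towards P on the a side
  if (sum((ctr(P) - mid) * en) < 0) en <- -en
  newa <- mid + 0.5 * l_new * en     # vertex kept by P
  newb <- mid - 0.5 * l_new * en     # vertex kept by Q
  remove_v <- function(ids, v) ids[ids != v]
  insert_after <- function(ids, anchor, v) {
    k <- match(anchor, ids)
    append(ids, v, after = k)
  }
  insert_before <- function(ids, anchor, v) {
    k <- match(anchor, ids)
    append(ids, v, after = k - 1L)
  }
  cells <- mesh$cells
  # P keeps a, Q keeps b
  cells[[P]] <- remove_v(cells[[P]], b)
  cells[[Q]] <- remove_v(cells[[Q]], a)
  if (length(cells[[P]]) < 3L || length(cells[[Q]]) < 3L) return(NULL)
  # R gains b next to a, on the Q side of a
  idsR <- cells[[R]]
  kR <- match(a, idsR)
  nb1 <- idsR[if (kR == length(idsR)) 1L else kR + 1L]
  nb2 <- idsR[if (kR == 1L) length(idsR) else kR - 1L]
  inQ <- c(nb1 %in% cells[[Q]] || nb1 == b, nb2 %in% cells[[Q]] || nb2 == b)
  if (inQ[1] && !inQ[2]) cells[[R]] <- insert_after(idsR, a, b)
  else if (inQ[2] && !inQ[1]) cells[[R]] <- insert_before(idsR, a, b)
  else return(NULL)
  # S gains a next to b, on the P side of b
  idsS <- cells[[S]]
  kS <- match(b, idsS)
  nb1 <- idsS[if (kS == length(idsS)) 1L else kS + 1L]
  nb2 <- idsS[if (kS == 1L) length(idsS) else kS - 1L]
  inP <- c(nb1 %in% cells[[P]] || nb1 == a, nb2 %in% cells[[P]] || nb2 == a)
  if (inP[1] && !inP[2]) cells[[S]] <- insert_after(idsS, b, a)
  else if (inP[2] && !inP[1]) cells[[S]] <- insert_before(idsS, b, a)
  else return(NULL)
  mesh$cells <- cells
  mesh$vertices[a, ] <- newa - box * floor(newa / box)
  mesh$vertices[b, ] <- newb - box * floor(newb / box)
  refresh_offsets(mesh)
}


# Attempt one T1 on the shortest interior edge below the threshold (or on
# the shortest edge outright when forced); NULL if none succeeded.
try_t1_scan <- function(mesh, l_thr, force_shortest = FALSE) {
  ed <- mesh_edges(mesh)
  d <- mesh$vertices[ed$v1, , drop = FALSE] - mesh$vertices[ed$v2, , drop = FALSE]
  d <- d - round(d / mesh$box) * mesh$box
  len <- sqrt(rowSums(d^2))
  interior <- !is.na(ed$cell_b)
  cand <- which(interior & (len < l_thr | (force_shortest & len < 3 * l_thr)))
  if (!length(cand)) return(NULL)
  for (k in cand[order(len[cand])]) {
    res <- t1_swap(mesh, ed$v1[k], ed$v2[k], 1.5 * l_thr)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' Relax a vertex mesh with FIRE
#'
#' Fast inertial relaxation engine with backtracking (a step that would
#' raise the energy is rejected, the inertial velocity reset and the
#' timestep reduced, so the reported energy is non-increasing), plus T1
#' edge swaps whenever an interior edge shrinks below `0.04 * sqrt(mean
#' A0)` (re-expanded to 1.5x the threshold).
#'
#' @param mesh A `vertex_mesh`.
#' @param tol Convergence threshold on the maximum vertex force norm.
#' @param max_iter Iteration cap.
#' @param dt0 Initial timestep (default `0.02`).
#' @param t1_every Check for T1 swaps every this many iterations.
#' @return The relaxed mesh, with attributes `converged`, `iterations`,
#'   `energy` (trace of accepted energies; `NA` marks a T1 topology change,
#'   which starts a new descent segment), `n_t1`.
#' @export
fire_minimize <- function(mesh, tol = 1e-3, max_iter = 2000L, dt0 = 0.02,
                          t1_every = 10L) {
  alpha0 <- 0.1; f_inc <- 1.1; f_dec <- 0.5; n_min <- 5L
  dt <- dt0; dt_max <- 10 * dt0
  alpha <- alpha0
  v <- matrix(0, nrow(mesh$vertices), 2L)
  e_prev <- tissue_energy(mesh)
  e_trace <- e_prev
  since_neg <- 0L
  n_t1 <- 0L
  l_thr <- 0.04 * sqrt(mean(mesh$A0))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Fm <- -tissue_gradient(mesh)
    fmax <- max(sqrt(rowSums(Fm^2)))
    if (fmax < tol) { converged <- TRUE; break }
    p <- sum(Fm * v)
    if (p > 0) {
      since_neg <- since_neg + 1L
      nv <- sqrt(sum(v^2)); nf <- sqrt(sum(Fm^2))
      v <- (1 - alpha) * v + alpha * Fm * (nv / max(nf, 1e-14))
      if (since_neg > n_min) {
        dt <- min(dt * f_inc, dt_max)
        alpha <- alpha * 0.99
      }
    } else {
      v[] <- 0
      dt <- dt * f_dec
      alpha <- alpha0
      since_neg <- 0L
    }
    v <- v + dt * Fm
    old_vertices <- mesh$vertices
    step <- dt * v
    smax <- sqrt(max(rowSums(step^2)))
    if (smax > 0.5 * sqrt(mean(mesh$A0))) step <- step * (0.5 * sqrt(mean(mesh$A0)) / smax)
    mesh$vertices <- mesh$vertices + step
    mesh$vertices <- mesh$vertices - mesh$box * floor(mesh$vertices / mesh$box)
    mesh <- refresh_offsets(mesh)
    e_new <- tissue_energy(mesh)
    if (e_new > e_prev + 1e-12) {
      # backtrack: reject the move
      mesh$vertices <- old_vertices
      mesh <- refresh_offsets(mesh)
      v[] <- 0
      dt <- dt * f_dec
      alpha <- alpha0
      since_neg <- 0L
      # a collapsing timestep signals a topological kink (an edge pinched
      # to zero length): resolve it with a T1 instead of grinding down
      if (dt < 0.02 * dt0) {
        res <- try_t1_scan(mesh, l_thr, force_shortest = dt < 1e-6 * dt0)
        if (!is.null(res)) {
          mesh <- res
          n_t1 <- n_t1 + 1L
          e_prev <- tissue_energy(mesh)
          e_trace <- c(e_trace, NA_real_)
          dt <- 0.25 * dt0
          next
        }
      }
      if (dt < 1e-9 * dt0) break
      next
    }
    e_prev <- e_new
    e_trace <- c(e_trace, e_new)
    if (it %% t1_every == 0L) {
      ed <- mesh_edges(mesh)
      d <- mesh$vertices[ed$v1, , drop = FALSE] - mesh$vertices[ed$v2, , drop = FALSE]
      d <- d - round(d / mesh$box) * mesh$box
      len <- sqrt(rowSums(d^2))
      short <- which(len < l_thr & !is.na(ed$cell_b))
      for (k in short) {
        res <- t1_swap(mesh, ed$v1[k], ed$v2[k], 1.5 * l_thr)
        if (!is.null(res)) {
          e_try <- tissue_energy(res)
          mesh <- res
          n_t1 <- n_t1 + 1L
          e_prev <- e_try
          e_trace <- c(e_trace, NA_real_)  # topology change: new descent segment
          v[] <- 0
          dt <- 0.25 * dt0
          break  # edge list is stale after a swap
        }
      }
    }
  }
  if (!converged)
    warning(sprintf("FIRE did not reach tol = %g in %d iterations (max force ~ %.3g)",
                    tol, max_iter, max(sqrt(rowSums(tissue_gradient(mesh)^2)))))
  attr(mesh, "converged") <- converged
  attr(mesh, "iterations") <- it
  attr(mesh, "energy") <- e_trace
  attr(mesh, "n_t1") <- n_t1
  mesh
}
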