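#' Labeled aggregate container
#'
#' Bundles positions and type labels of a multicellular aggregate for the
#' sorting statistics. Positions may be cell centres (one row per cell) or
#' subcellular elements (with `cell_id` mapping rows to cells; only rows
#' with `cortex = TRUE` participate in surface detection when provided).
#'
#' @param positions Numeric matrix (n x 3 or n x 2) of coordinates.
#' @param cell_id Integer cell membership per row (defaults to one row =
#'   one cell).
#' @param cell_type Character/factor per cell, two types for sorting
#'   statistics; conventionally `"EPI"` and `"PrE"`.
#' @param cortex Optional logical per row; rows eligible as surface
#'   elements.
#' @param signal Optional numeric per cell (e.g. reporter intensity) for
#'   [radial_enrichment()].
#' @return An object of class `labeled_aggregate`.
#' @export
labeled_aggregate <- function(positions, cell_type, cell_id = NULL,
                              cortex = NULL, signal = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) == 2L) positions <- cbind(positions, 0)
  n <- nrow(positions)
  if (is.null(cell_id)) cell_id <- seq_len(n)
  cell_id <- as.integer(cell_id)
  stopifnot(length(cell_id) == n)
  cells <- sort(unique(cell_id))
  if (length(cell_type) != length(cells))
    stop("cell_type must have one entry per cell")
  if (is.null(cortex)) cortex <- rep(TRUE, n)
  structure(list(positions = positions, cell_id = cell_id,
                 cells = cells, cell_type = as.character(cell_type),
                 cortex = as.logical(cortex), signal = signal),
            class = "labeled_aggregate")
}

# Uniformly distributed directions on the sphere (spherical Fibonacci).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5)) * 2
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Identify aggregate-external elements
#'
#' Samples the aggregate's support function on a set of approximately
#' uniform sphere directions (spherical Fibonacci set): each direction is
#' credited to the eligible element extending farthest along it. The winner
#' set samples the convex hull of the element cloud, and the per-cell
#' count of directions won is proportional to the solid angle -- hence the
#' exposed surface area -- that the cell presents to the outside.
#'
#' @param agg A `labeled_aggregate`.
#' @param n_bins Number of sampling directions (default
#'   `max(256, 16 * n_cells)`).
#' @return Integer vector: per-cell counts of directions won (named by
#'   cell), with attribute `external_rows` (row indices that won at least
#'   one direction).
#' @export
external_elements <- function(agg, n_bins = NULL) {
  stopifnot(inherits(agg, "labeled_aggregate"))
  pos <- agg$positions[agg$cortex, , drop = FALSE]
  ids <- agg$cell_id[agg$cortex]
  rows <- which(agg$cortex)
  if (nrow(pos) == 0L) stop("no eligible surface elements")
  if (is.null(n_bins)) n_bins <- max(256L, 16L * length(agg$cells))
  ctr <- colMeans(pos)
  v <- sweep(pos, 2L, ctr)
  dirs <- fibonacci_directions(n_bins)
  support <- v %*% t(dirs)     # projection of every element on every direction
  winner <- max.col(t(support), ties.method = "first")
  counts <- table(factor(ids[winner], levels = agg$cells))
  out <- as.integer(counts)
  names(out) <- as.character(agg$cells)
  attr(out, "external_rows") <- rows[sort(unique(winner))]
  out
}

#' External-surface fraction of one cell type
#'
#' The fraction XS of the aggregate's exposed surface (counted in external
#' elements, see [external_elements()]) contributed by cells of
#' `type_outside` — by convention the PrE lineage, which sorts to the
#' exterior.
#'
#' @param agg A `labeled_aggregate` with at least two cells.
#' @param type_outside Label of the type expected outside (default
#'   `"PrE"`).
#' @param n_bins Direction bins passed to [external_elements()].
#' @return XS in `[0, 1]`.
#' @export
external_surface_fraction <- function(agg, type_outside = "PrE", n_bins = NULL) {
  stopifnot(inherits(agg, "labeled_aggregate"))
  if (length(agg$cells) < 2L) stop("need at least two cells")
  counts <- external_elements(agg, n_bins)
  total <- sum(counts)
  if (total == 0L) stop("internal error: no external elements found")
  sum(counts[agg$cell_type == type_outside]) / total
}

#' Randomization null for the external-surface fraction
#'
#' Holds the spatial arrangement (hence each cell's external-surface
#' count) fixed, randomly reallocates the type labels preserving the type
#' counts, and recomputes XS for each shuffle; returns the mean and SD over
#' shuffles. Because the geometry is fixed, XS under a shuffle is the
#' label-permuted count-weighted share, so the null costs one surface
#' detection regardless of `n_shuffles`.
#'
#' @param agg A `labeled_aggregate` with both types present.
#' @param n_shuffles Number of label shuffles (the reference analysis uses
#'   100,000).
#' @param seed Integer seed; the draw is deterministic given it.
#' @param type_outside Type counted as outside (default `"PrE"`).
#' @param n_bins Direction bins for surface detection.
#' @return List with `mu`, `sigma`, `n_shuffles`, plus `xs_null` (the
#'   shuffled XS values, invisibly usable for diagnostics).
#' @export
randomization_null <- function(agg, n_shuffles = 1e5, seed = 1L,
                               type_outside = "PrE", n_bins = NULL) {
  stopifnot(inherits(agg, "labeled_aggregate"))
  types <- agg$cell_type
  n_out <- sum(types == type_outside)
  if (n_out == 0L || n_out == length(types))
    stop("both cell types must be present for a randomization null")
  counts <- as.numeric(external_elements(agg, n_bins))
  total <- sum(counts)
  n_cells <- length(counts)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  xs <- vapply(seq_len(n_shuffles), function(i)
    sum(counts[sample.int(n_cells, n_out)]) / total, 0)
  list(mu = mean(xs), sigma = sd_pop(xs), n_shuffles = as.integer(n_shuffles),
       xs_null = xs)
}

#' Sorting index
#'
#' Randomization-normalized external-surface fraction:
#' \deqn{SI = (XS - \mu) / (4\sigma)} with \eqn{\mu,\sigma} from the
#' label-shuffling null at fixed geometry. 0 indicates random positioning,
#' +1 complete sorting with the outside type (PrE) enveloping the
#' aggregate, -1 the inverted arrangement.
#'
#' @param XS Observed external-surface fraction.
#' @param mu,sigma Null mean and SD (see [randomization_null()]);
#'   `sigma > 0` required.
#' @return The sorting index.
#' @export
sorting_index <- function(XS, mu, sigma) {
  chk_num(XS, "XS", 0, 1)
  chk_num(mu, "mu")
  chk_num(sigma, "sigma", 0)
  if (sigma == 0) stop("sigma must be positive: degenerate null")
  (XS - mu) / (4 * sigma)
}

#' One-call sorting index of an aggregate
#'
#' Convenience wrapper: XS, the shuffling null, and SI in one call, reusing
#' a single surface detection.
#'
#' @inheritParams randomization_null
#' @return List with `XS`, `mu`, `sigma`, `SI`, `n_shuffles`.
#' @export
sorting_index_of <- function(agg, n_shuffles = 1e5, seed = 1L,
                             type_outside = "PrE", n_bins = NULL) {
  counts <- external_elements(agg, n_bins)
  total <- sum(counts)
  XS <- sum(counts[agg$cell_type == type_outside]) / total
  nn <- randomization_null(agg, n_shuffles, seed, type_outside, n_bins)
  list(XS = XS, mu = nn$mu, sigma = nn$sigma,
       SI = sorting_index(XS, nn$mu, nn$sigma),
       n_shuffles = nn$n_shuffles)
}

#' Demixing parameter of a binary mixture
#'
#' Normalized same-type neighbour enrichment on an adjacency graph:
#' \deqn{DP = \max\left(0, \frac{\langle f_{same}\rangle - f_{rand}}{1 - f_{rand}}\right)}
#' where \eqn{f_{same}} is each cell's fraction of same-type neighbours and
#' \eqn{f_{rand}} its expectation under random labeling at the observed
#' type counts, \eqn{[n_1(n_1-1)+n_2(n_2-1)]/[n(n-1)]}. 0 corresponds to a
#' mixed tissue, 1 to maximal segregation.
#'
#' @param adjacency Two-column integer matrix of neighbouring cell pairs
#'   (undirected; duplicates ignored), or a logical/numeric adjacency
#'   matrix.
#' @param types Character/factor vector of cell types (exactly two levels
#'   present).
#' @return DP in `[0, 1]`, with attributes `f_same` and `f_rand`.
#' @export
demixing_parameter <- function(adjacency, types) {
  types <- as.character(types)
  n <- length(types)
  lv <- unique(types)
  if (length(lv) != 2L) stop("exactly two cell types must be present")
  if (is.matrix(adjacency) && nrow(adjacency) == n && ncol(adjacency) == n) {
    idx <- which(adjacency != 0 & upper.tri(adjacency), arr.ind = TRUE)
    pairs <- idx
  } else {
    pairs <- unique(t(apply(as.matrix(adjacency), 1L, sort)))
  }
  if (nrow(pairs) == 0L) stop("adjacency has no edges")
  deg <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n)
  same <- types[pairs[, 1]] == types[pairs[, 2]]
  same_cnt <- tabulate(c(pairs[same, 1], pairs[same, 2]), nbins = n)
  isolated <- deg == 0L
  if (any(isolated)) {
    warning(sum(isolated), " cell(s) with no neighbours excluded from DP")
  }
  f_same <- mean(same_cnt[!isolated] / deg[!isolated])
  n1 <- sum(types == lv[1]); n2 <- n - n1
  f_rand <- (n1 * (n1 - 1) + n2 * (n2 - 1)) / (n * (n - 1))
  dp <- max(0, (f_same - f_rand) / (1 - f_rand))
  attr(dp, "f_same") <- f_same
  attr(dp, "f_rand") <- f_rand
  dp
}

#' Radial enrichment of a labeled signal
#'
#' Dipole-moment-style sorting readout for aggregates with a graded
#' reporter: the signal-weighted mean distance of labeled cells from the
#' aggregate centroid, divided by the unweighted mean distance over all
#' cells. 1 means the label is distributed like the bulk; values above 1
#' indicate enrichment toward the outside.
#'
#' @param positions Cell-centre matrix (n x 2 or n x 3).
#' @param signal Non-negative weights per cell (binarized labels or
#'   intensities); must not be all zero.
#' @return The radial enrichment R.
#' @export
radial_enrichment <- function(positions, signal) {
  positions <- as.matrix(positions)
  stopifnot(length(signal) == nrow(positions))
  if (any(signal < 0)) stop("signal must be non-negative")
  if (sum(signal) == 0) stop("empty label set: all signal weights are zero")
  ctr <- colMeans(positions)
  d <- sqrt(rowSums(sweep(positions, 2L, ctr)^2))
  (sum(signal * d) / sum(signal)) / mean(d)
}

#' Radial enrichment by expression tertile
#'
#' Mirrors the reporter-thresholding analysis of mixed aggregates: the
#' bottom half of the expression distribution is treated as unlabeled
#' control and discarded; the top half is split into tertiles (low / mid /
#' high expressers), each binarized and scored with [radial_enrichment()].
#'
#' @param positions Cell-centre matrix.
#' @param expression Numeric reporter level per cell.
#' @return Data frame with columns `group` (low/mid/high) and `R`.
#' @export
radial_enrichment_tertiles <- function(positions, expression) {
  positions <- as.matrix(positions)
  stopifnot(length(expression) == nrow(positions))
  keep <- expression > stats::median(expression)
  expr_top <- expression[keep]
  qs <- stats::quantile(expr_top, c(1 / 3, 2 / 3), names = FALSE)
  grp <- cut(expr_top, c(-Inf, qs, Inf), labels = c("low", "mid", "high"))
  out <- data.frame(group = c("low", "mid", "high"), R = NA_real_)
  for (g in out$group) {
    w <- numeric(nrow(positions))
    w[keep][grp == g] <- 1
    out$R[out$group == g] <- radial_enrichment(positions, w)
  }
  out
}
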