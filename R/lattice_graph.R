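# Weighted pixel-lattice graph, Laplacian and seed-partitioned blocks.

#' Build the weighted lattice graph of an image
#'
#' One node per pixel (row-major indexing, see [node_index()]); one edge per
#' neighboring pixel pair under 4- or 8-connectivity. Edge weights follow the
#' Gaussian-of-L1 form w_ij = exp(-beta * |g_i - g_j|) + epsilon_w. The
#' positive floor `epsilon_w` keeps the lattice connected (and the reduced
#' Laplacian nonsingular) even where the exponential underflows.
#'
#' @param grid intensity grid (matrix in \[0, 1\], see [as_intensity_grid()]).
#' @param beta nonnegative contrast parameter; the published operating range
#'   on unit-scale intensities is roughly 230-340 (default 310).
#' @param connectivity 4 (default) or 8.
#' @param epsilon_w nonnegative additive weight floor (default 1e-6).
#' @return object of class `lattice_graph`: list with `rows`, `cols`,
#'   `n_nodes`, `edges` (two-column matrix, i < j), `weights`, `beta`,
#'   `connectivity`, `epsilon_w`.
#' @export
build_lattice_graph <- function(grid, beta = 310, connectivity = 4, epsilon_w = 1e-6) {
  validate_intensity_grid(grid)
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta < 0) {
    ap_stop("beta must be a single nonnegative number", "apseg_invalid_parameter")
  }
  if (!(connectivity %in% c(4, 8))) {
    ap_stop("connectivity must be 4 or 8", "apseg_invalid_parameter")
  }
  if (!is.numeric(epsilon_w) || length(epsilon_w) != 1 || epsilon_w < 0) {
    ap_stop("epsilon_w must be a single nonnegative number", "apseg_invalid_parameter")
  }
  rows <- nrow(grid); cols <- ncol(grid)
  n <- rows * cols

  idx <- matrix(seq_len(n), rows, cols, byrow = TRUE)
  ei <- integer(0); ej <- integer(0)
  if (cols > 1) {  # horizontal neighbors
    a <- idx[, -cols, drop = FALSE]; b <- idx[, -1, drop = FALSE]
    ei <- c(ei, vec_rm(a)); ej <- c(ej, vec_rm(b))
  }
  if (rows > 1) {  # vertical neighbors
    a <- idx[-rows, , drop = FALSE]; b <- idx[-1, , drop = FALSE]
    ei <- c(ei, vec_rm(a)); ej <- c(ej, vec_rm(b))
  }
  if (connectivity == 8 && rows > 1 && cols > 1) {
    a <- idx[-rows, -cols, drop = FALSE]; b <- idx[-1, -1, drop = FALSE]     # down-right
    ei <- c(ei, vec_rm(a)); ej <- c(ej, vec_rm(b))
    a <- idx[-rows, -1, drop = FALSE]; b <- idx[-1, -cols, drop = FALSE]     # down-left
    ei <- c(ei, vec_rm(a)); ej <- c(ej, vec_rm(b))
  }
  lo <- pmin(ei, ej); hi <- pmax(ei, ej)

  g <- vec_rm(grid)
  w <- exp(-beta * abs(g[lo] - g[hi])) + epsilon_w

  structure(list(rows = rows, cols = cols, n_nodes = n,
                 edges = cbind(i = lo, j = hi), weights = w,
                 beta = beta, connectivity = connectivity,
                 epsilon_w = epsilon_w),
            class = "lattice_graph")
}

#' Sparse graph Laplacian of a lattice graph
#'
#' L(i,i) = sum_k w_ik, L(i,j) = -w_ij for adjacent i, j, zero otherwise.
#'
#' @param graph a `lattice_graph`.
#' @return symmetric sparse matrix (`Matrix::dsCMatrix`).
#' @export
graph_laplacian <- function(graph) {
  n <- graph$n_nodes
  W <- Matrix::sparseMatrix(i = graph$edges[, 1], j = graph$edges[, 2],
                            x = graph$weights, dims = c(n, n), symmetric = TRUE)
  d <- Matrix::rowSums(W)
  Matrix::forceSymmetric(Matrix::Diagonal(n, d) - W)
}

#' Seed set for a two-label segmentation
#'
#' @param foreground,background integer node indices (see [node_index()]);
#'   both nonempty, disjoint.
#' @return object of class `seed_set`: list with `foreground`, `background`,
#'   `marked` (foreground then background) and `m`, the |marked| x 2 indicator
#'   matrix with columns `f`, `b`.
#' @export
seed_set <- function(foreground, background) {
  foreground <- as.integer(foreground); background <- as.integer(background)
  if (length(foreground) < 1 || length(background) < 1 ||
      anyNA(foreground) || anyNA(background)) {
    ap_stop("need at least one foreground and one background seed",
            "apseg_invalid_seed")
  }
  if (anyDuplicated(foreground) || anyDuplicated(background) ||
      length(intersect(foreground, background)) > 0) {
    ap_stop("foreground and background seeds must be disjoint and unique",
            "apseg_invalid_seed")
  }
  marked <- c(foreground, background)
  m <- cbind(f = rep(c(1, 0), c(length(foreground), length(background))),
             b = rep(c(0, 1), c(length(foreground), length(background))))
  structure(list(foreground = foreground, background = background,
                 marked = marked, m = m),
            class = "seed_set")
}

#' Laplacian blocks partitioned by the seed set
#'
#' Partitions the node set into marked (seeds, in the order foreground then
#' background) and unmarked nodes and extracts the blocks used by the linear
#' systems: `L_U` (unmarked diagonal block) and `B` (marked x unmarked
#' off-diagonal block). The permutation is retained so solutions on unmarked
#' nodes can be scattered back to image order.
#'
#' @param graph a `lattice_graph`.
#' @param seeds a `seed_set` with node indices in `1..n_nodes`.
#' @return object of class `graph_operators`: list with `L`, `L_U`, `B`,
#'   `marked`, `unmarked`, `m`, `rows`, `cols`.
#' @export
graph_operators <- function(graph, seeds) {
  if (!inherits(seeds, "seed_set")) {
    ap_stop("seeds must be a seed_set", "apseg_invalid_seed")
  }
  n <- graph$n_nodes
  if (any(seeds$marked < 1L) || any(seeds$marked > n)) {
    ap_stop("seed node indices out of range", "apseg_invalid_seed")
  }
  L <- graph_laplacian(graph)
  marked <- seeds$marked
  unmarked <- setdiff(seq_len(n), marked)
  structure(list(L = L,
                 L_U = L[unmarked, unmarked, drop = FALSE],
                 B = L[marked, unmarked, drop = FALSE],
                 marked = marked, unmarked = unmarked, m = seeds$m,
                 rows = graph$rows, cols = graph$cols),
            class = "graph_operators")
}
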