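# Independent oracles, kept deliberately naive: dense constructions by
# coordinate loops, never through the package's sparse code paths.

# Dense Laplacian built by scanning all pixel pairs for adjacency.
dense_laplacian <- function(grid, beta, epsilon_w = 0, connectivity = 4) {
  rows <- nrow(grid); cols <- ncol(grid)
  n <- rows * cols
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ri <- (i - 1) %/% cols + 1; ci <- (i - 1) %% cols + 1
    for (j in seq_len(n)) {
      if (i == j) next
      rj <- (j - 1) %/% cols + 1; cj <- (j - 1) %% cols + 1
      dr <- abs(ri - rj); dc <- abs(ci - cj)
      adj <- if (connectivity == 4) dr + dc == 1 else max(dr, dc) == 1
      if (adj) {
        L[i, j] <- -(exp(-beta * abs(grid[ri, ci] - grid[rj, cj])) + epsilon_w)
      }
    }
  }
  diag(L) <- -rowSums(L)
  L
}

# Reference random-walker probabilities by dense direct solve.
rw_reference <- function(grid, fg, bg, beta, epsilon_w = 1e-6) {
  L <- dense_laplacian(grid, beta, epsilon_w)
  n <- nrow(L)
  marked <- c(fg, bg)
  unmarked <- setdiff(seq_len(n), marked)
  m <- cbind(f = as.numeric(marked %in% fg), b = as.numeric(marked %in% bg))
  x <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("f", "b")))
  x[marked, ] <- m
  B <- L[marked, unmarked, drop = FALSE]
  LU <- L[unmarked, unmarked, drop = FALSE]
  for (lab in c("f", "b")) {
    x[unmarked, lab] <- solve(LU, -as.numeric(t(B) %*% m[, lab]))
  }
  x
}

# Brute-force confusion counts by an explicit double loop.
confusion_bruteforce <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (r in seq_len(nrow(pred))) {
    for (c in seq_len(ncol(pred))) {
      p <- pred[r, c]; t <- truth[r, c]
      if (p == 1 && t == 1) tp <- tp + 1L
      else if (p == 1 && t == 0) fp <- fp + 1L
      else if (p == 0 && t == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

random_grid <- function(rows, cols, seed) {
  withr::with_seed(seed, matrix(runif(rows * cols), rows, cols))
}

# Random disjoint seed node sets on an n-node graph.
random_seeds <- function(n, n_fg, n_bg, seed) {
  withr::with_seed(seed, {
    picks <- sample(n, n_fg + n_bg)
    seed_set(picks[seq_len(n_fg)], picks[n_fg + seq_len(n_bg)])
  })
}

# Random attraction field on a grid: random blob prior placed at a random
# interior pixel. Returns NULL if the thresholded support is empty.
random_field <- function(grid, seed, gamma = 0.6) {
  rows <- nrow(grid); cols <- ncol(grid)
  drawn <- withr::with_seed(seed, {
    corpus <- lapply(1:4, function(k) {
      m <- matrix(0, rows, cols)
      cr <- sample(2:(rows - 1), 1); cc <- sample(2:(cols - 1), 1)
      rad <- sample(1:max(1, floor(min(rows, cols) / 4)), 1)
      for (r in seq_len(rows)) for (c in seq_len(cols)) {
        if ((r - cr)^2 + (c - cc)^2 <= rad^2) m[r, c] <- 1
      }
      if (!any(m == 1)) m[cr, cc] <- 1
      m
    })
    list(prior = train_shape_prior(corpus, gamma = gamma),
         seed_px = c(sample(2:(rows - 1), 1), sample(2:(cols - 1), 1)))
  })
  if (!any(drawn$prior$threshold_matrix > 0)) return(NULL)
  attraction_factors(place_prior(drawn$prior, drawn$seed_px, grid), grid)
}

# A 1x3 constant image whose middle pixel is the single unknown, with unit
# edge weights, one fg seed (node 1), one bg seed (node 3), and a 1-cell
# attraction region at the unknown with a = 1 and tau^f = 0.8.
micro_instance <- function() {
  grid <- matrix(0, 1, 3)
  graph <- build_lattice_graph(grid, beta = 310, epsilon_w = 0)
  seeds <- seed_set(1L, 3L)
  ops <- graph_operators(graph, seeds)
  prior <- threshold_prior(shape_probability(list(
    matrix(1, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1),
    matrix(1, 1, 1), matrix(0, 1, 1))), 0.5)  # SP = 4/5 = 0.8 on a 1x1 canvas
  field <- attraction_factors(place_prior(prior, c(1, 2), grid), grid)
  list(grid = grid, graph = graph, seeds = seeds, ops = ops, field = field)
}

# Zero out an attraction field so the region is empty (A = 0 path).
empty_field <- function(field) {
  field$region[] <- FALSE
  field$shifted_t[] <- 0
  field$factors[] <- 0
  field
}
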