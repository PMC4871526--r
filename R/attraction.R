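# Attraction field: prior placement at the seed, attraction factors,
# range bases and the diagonal attraction incidence matrix.

#' Place a shape prior at the foreground seed
#'
#' The threshold matrix is translated so that its canvas center coincides
#' with the seed pixel (the canvas center equals the calibrated centroid by
#' construction). Cells falling outside the image are clipped. The attraction
#' region is the nonzero support of the shifted threshold matrix.
#'
#' @param prior a thresholded `shape_prior`.
#' @param seed foreground seed as `c(row, col)` (1-based).
#' @param grid intensity grid (defines the image dimensions and the seed
#'   intensity).
#' @return object of class `attraction_field`: list with `region` (logical
#'   matrix), `shifted_t` (numeric matrix, 0 outside the region), `factors`
#'   (NULL until [attraction_factors()]), `seed_rc`, `seed` (node index),
#'   `seed_intensity`, `rows`, `cols`.
#' @export
place_prior <- function(prior, seed, grid) {
  validate_intensity_grid(grid)
  if (!inherits(prior, "shape_prior") || is.null(prior$threshold_matrix)) {
    ap_stop("prior must be a thresholded shape_prior (see threshold_prior)",
            "apseg_invalid_input")
  }
  if (!any(prior$threshold_matrix > 0)) {
    ap_stop("shape prior support is empty at this gamma", "apseg_empty_prior")
  }
  rows <- nrow(grid); cols <- ncol(grid)
  seed <- as.integer(seed)
  if (length(seed) != 2 || anyNA(seed) ||
      seed[1] < 1 || seed[1] > rows || seed[2] < 1 || seed[2] > cols) {
    ap_stop("seed must be c(row, col) inside the image", "apseg_invalid_seed")
  }
  tm <- prior$threshold_matrix
  ctr <- canvas_center(nrow(tm), ncol(tm))
  # canvas cell (i, j) lands on image pixel (seed + (i,j) - center)
  dr <- seed[1] - ctr[1]; dc <- seed[2] - ctr[2]
  ci <- seq_len(nrow(tm)); cj <- seq_len(ncol(tm))
  keep_i <- ci[ci + dr >= 1 & ci + dr <= rows]
  keep_j <- cj[cj + dc >= 1 & cj + dc <= cols]
  shifted <- matrix(0, rows, cols)
  if (length(keep_i) && length(keep_j)) {
    shifted[keep_i + dr, keep_j + dc] <- tm[keep_i, keep_j]
  }
  structure(list(region = shifted > 0, shifted_t = shifted, factors = NULL,
                 seed_rc = seed, seed = node_index(seed[1], seed[2], cols),
                 seed_intensity = grid[seed[1], seed[2]],
                 rows = rows, cols = cols),
            class = "attraction_field")
}

#' Attraction factors
#'
#' a_i = exp(-sharpness * |g_i - g_s|) on region pixels, 0 elsewhere, where
#' g_s is the seed intensity. On unit-scale intensities the factors lie in
#' \[exp(-sharpness), 1\].
#'
#' @param field an `attraction_field` from [place_prior()].
#' @param grid the intensity grid.
#' @param sharpness optional multiplier on the intensity distance
#'   (default 1, the published form).
#' @return the field with `factors` filled.
#' @export
attraction_factors <- function(field, grid, sharpness = 1) {
  validate_intensity_grid(grid)
  if (!inherits(field, "attraction_field")) {
    ap_stop("field must be an attraction_field", "apseg_invalid_input")
  }
  if (!is.numeric(sharpness) || length(sharpness) != 1 || sharpness < 0) {
    ap_stop("sharpness must be a single nonnegative number", "apseg_invalid_parameter")
  }
  a <- exp(-sharpness * abs(grid - field$seed_intensity))
  field$factors <- a * field$region
  field
}

#' Range base vector for one label
#'
#' For region pixels, tau^f equals the shifted threshold matrix and
#' tau^b = 1 - tau^f; both are 0 outside the region. With `eps_tau > 0` the
#' values inside the region are floored (needed by the Pearson variant, whose
#' system matrix contains 1/tau).
#'
#' @param field an `attraction_field`.
#' @param label `"f"` or `"b"`.
#' @param eps_tau floor applied inside the region (default 0: the exact
#'   published values).
#' @return numeric vector of length rows*cols in node (row-major) order.
#' @export
range_base <- function(field, label, eps_tau = 0) {
  if (!inherits(field, "attraction_field")) {
    ap_stop("field must be an attraction_field", "apseg_invalid_input")
  }
  if (!is.character(label) || length(label) != 1 || !(label %in% c("f", "b"))) {
    ap_stop("label must be \"f\" or \"b\"", "apseg_invalid_label")
  }
  tvec <- vec_rm(field$shifted_t)
  reg <- vec_rm(field$region)
  tau <- if (label == "f") tvec else 1 - tvec
  tau[!reg] <- 0
  if (eps_tau > 0) tau[reg] <- pmax(tau[reg], eps_tau)
  tau
}

#' Diagonal attraction incidence matrix
#'
#' A(i, i) = a_i for region nodes, zero elsewhere.
#'
#' @param field an `attraction_field` with factors computed.
#' @return sparse diagonal n x n matrix.
#' @export
attraction_matrix <- function(field) {
  if (!inherits(field, "attraction_field") || is.null(field$factors)) {
    ap_stop("field must have factors (see attraction_factors)", "apseg_invalid_input")
  }
  Matrix::Diagonal(field$rows * field$cols, vec_rm(field$factors))
}
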