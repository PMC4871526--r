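# Shape prior learning: centroid calibration, shape probability matrix,
# thresholding, and serialization.

#' Centroid of a binary mask
#'
#' Arithmetic mean of the foreground pixel coordinates.
#'
#' @param mask binary 0/1 matrix.
#' @return numeric vector `c(row, col)` (1-based).
#' @export
mask_centroid <- function(mask) {
  check_mask(mask)
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) ap_stop("mask has no foreground pixels", "apseg_empty_mask")
  c(row = mean(fg[, 1]), col = mean(fg[, 2]))
}

canvas_center <- function(rows, cols) {
  # 0-based center floor((n-1)/2), expressed 1-based
  c(floor((rows - 1) / 2) + 1L, floor((cols - 1) / 2) + 1L)
}

#' Calibrate masks to a common canvas center
#'
#' Each mask is translated by the integer shift that moves its rounded
#' centroid (halves round down) to the canvas center. Pixels shifted outside
#' the canvas are clipped with a warning; no scaling or interpolation is
#' performed, so masks stay binary.
#'
#' @param masks list of binary 0/1 matrices, each with at least one
#'   foreground pixel.
#' @param canvas_rows,canvas_cols common canvas; defaults to the maximum mask
#'   dimensions in the corpus.
#' @return list of calibrated masks, all `canvas_rows x canvas_cols`.
#' @export
calibrate_masks <- function(masks, canvas_rows = NULL, canvas_cols = NULL) {
  if (!is.list(masks) || length(masks) == 0) {
    ap_stop("masks must be a nonempty list of binary matrices", "apseg_invalid_input")
  }
  lapply(masks, check_mask)
  if (is.null(canvas_rows)) canvas_rows <- max(vapply(masks, nrow, 1L))
  if (is.null(canvas_cols)) canvas_cols <- max(vapply(masks, ncol, 1L))
  ctr <- canvas_center(canvas_rows, canvas_cols)
  lapply(masks, function(m) {
    cen <- round_half_down(mask_centroid(m))
    shift <- ctr - cen
    fg <- which(m == 1, arr.ind = TRUE)
    r <- fg[, 1] + shift[1]; c <- fg[, 2] + shift[2]
    keep <- r >= 1 & r <= canvas_rows & c >= 1 & c <= canvas_cols
    if (!all(keep)) {
      warning(sprintf("calibrate_masks: %d pixel(s) clipped at the canvas border",
                      sum(!keep)))
    }
    out <- matrix(0, canvas_rows, canvas_cols)
    out[cbind(r[keep], c[keep])] <- 1
    out
  })
}

new_shape_prior <- function(counts, n_samples, gamma = NULL) {
  sp <- counts / n_samples
  p <- structure(list(sp = sp, counts = counts, n_samples = as.integer(n_samples),
                      canvas_rows = nrow(sp), canvas_cols = ncol(sp),
                      gamma = NULL, threshold_matrix = NULL),
                 class = "shape_prior")
  if (!is.null(gamma)) p <- threshold_prior(p, gamma) else p
}

#' Shape probability matrix from calibrated masks
#'
#' SP(m, n) = Fr(m, n) / Ns, where Fr counts how many of the Ns calibrated
#' masks cover cell (m, n). Every entry is a multiple of 1/Ns.
#'
#' @param calibrated_masks list of binary masks sharing dimensions (see
#'   [calibrate_masks()]).
#' @return object of class `shape_prior` with `sp`, `counts`, `n_samples`,
#'   canvas dimensions; no threshold yet (see [threshold_prior()]).
#' @export
shape_probability <- function(calibrated_masks) {
  if (!is.list(calibrated_masks) || length(calibrated_masks) == 0) {
    ap_stop("need at least one mask", "apseg_invalid_input")
  }
  lapply(calibrated_masks, check_mask)
  dims <- vapply(calibrated_masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    ap_stop("calibrated masks must share dimensions", "apseg_invalid_input")
  }
  counts <- Reduce(`+`, calibrated_masks)
  new_shape_prior(counts, length(calibrated_masks))
}

#' Threshold a shape prior
#'
#' T(m, n) = SP(m, n) where SP(m, n) >= gamma (inclusive), 0 otherwise. The
#' nonzero support of T is the shape prior region.
#'
#' @param prior a `shape_prior`.
#' @param gamma threshold in \[0, 1\].
#' @return the prior with `gamma` and `threshold_matrix` filled.
#' @export
threshold_prior <- function(prior, gamma) {
  if (!inherits(prior, "shape_prior")) {
    ap_stop("prior must be a shape_prior", "apseg_invalid_input")
  }
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    ap_stop("gamma must lie in [0, 1]", "apseg_invalid_parameter")
  }
  prior$gamma <- gamma
  prior$threshold_matrix <- prior$sp * (prior$sp >= gamma)
  prior
}

#' Train a shape prior from a mask corpus
#'
#' Convenience wrapper: [calibrate_masks()] then [shape_probability()] then
#' [threshold_prior()].
#'
#' @param masks list of binary masks.
#' @param gamma probability threshold (default 0.8, the published operating
#'   point for the Pearson and L2 variants).
#' @param canvas_rows,canvas_cols optional common canvas.
#' @return a thresholded `shape_prior`.
#' @export
train_shape_prior <- function(masks, gamma = 0.8,
                              canvas_rows = NULL, canvas_cols = NULL) {
  threshold_prior(shape_probability(
    calibrate_masks(masks, canvas_rows, canvas_cols)), gamma)
}

#' Save a shape prior to a portable JSON container
#'
#' The integer overlap counts and Ns are stored (not the SP floats), so the
#' round-trip is bit-exact: SP is recomputed as counts/Ns on load.
#'
#' @param prior a `shape_prior`.
#' @param path output file.
#' @export
save_prior <- function(prior, path) {
  if (!inherits(prior, "shape_prior")) {
    ap_stop("prior must be a shape_prior", "apseg_invalid_input")
  }
  obj <- list(format = "apseg_shape_prior", version = 1L,
              canvas = c(prior$canvas_rows, prior$canvas_cols),
              n_samples = prior$n_samples,
              counts = as.integer(vec_rm(prior$counts)))
  if (!is.null(prior$gamma)) obj$gamma <- prior$gamma
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a shape prior saved by [save_prior()]
#'
#' @param path JSON file.
#' @return a `shape_prior` (thresholded if a gamma was stored).
#' @export
load_prior <- function(path) {
  if (!file.exists(path)) ap_stop(paste("no such file:", path), "apseg_format_error")
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) ap_stop(
                    paste("not a valid prior file:", conditionMessage(e)),
                    "apseg_format_error"))
  if (!identical(obj$format, "apseg_shape_prior") || !identical(as.integer(obj$version), 1L)) {
    ap_stop("unrecognized prior container format/version", "apseg_format_error")
  }
  canvas <- as.integer(obj$canvas); ns <- as.integer(obj$n_samples)
  counts <- as.numeric(obj$counts)
  if (length(canvas) != 2 || anyNA(canvas) || any(canvas < 1) ||
      is.na(ns) || ns < 1 || length(counts) != prod(canvas) ||
      anyNA(counts) || any(counts < 0) || any(counts > ns)) {
    ap_stop("prior file is corrupt: shape/count header mismatch", "apseg_format_error")
  }
  new_shape_prior(mat_rm(counts, canvas[1], canvas[2]), ns,
                  gamma = obj$gamma)
}
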