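# Internal helpers shared across modules.

# Classed error so callers/tests can discriminate failure modes.
ap_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "apseg_error", "error", "condition")))
}

#' Linear node index of a pixel
#'
#' Pixels are indexed row-major: node = (row - 1) * cols + col, with 1-based
#' rows and columns. This ordering is used for every vectorized quantity in
#' the package (graph nodes, range bases, probability fields).
#'
#' @param row,col 1-based pixel coordinates (vectors allowed).
#' @param cols number of image columns.
#' @return integer node indices.
#' @export
node_index <- function(row, col, cols) {
  as.integer((row - 1L) * cols + col)
}

#' Pixel coordinates of linear node indices
#'
#' Inverse of [node_index()].
#'
#' @param idx node indices.
#' @param cols number of image columns.
#' @return two-column integer matrix with columns `row`, `col`.
#' @export
node_rc <- function(idx, cols) {
  idx <- as.integer(idx)
  cbind(row = (idx - 1L) %/% cols + 1L, col = (idx - 1L) %% cols + 1L)
}

# Row-major vectorization (matches node ordering); R matrices are
# column-major so this is t() + as.vector.
vec_rm <- function(m) as.vector(t(m))

mat_rm <- function(v, rows, cols) matrix(v, rows, cols, byrow = TRUE)

# Round halves towards minus infinity: 2.5 -> 2, 2.51 -> 3.
round_half_down <- function(x) ceiling(x - 0.5)

is_binary_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m %in% c(0, 1))
}

check_mask <- function(mask, what = "mask") {
  if (!is_binary_matrix(mask)) {
    ap_stop(sprintf("%s must be a numeric matrix with values in {0, 1}", what),
            "apseg_invalid_input")
  }
  invisible(mask)
}
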