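# Viewfinder seed initialization: background frame + one foreground seed.

#' Automatic viewfinder seeding
#'
#' Builds the single-interaction seed layout: background seeds form a
#' rectangular frame at a fixed margin from the image border, and one
#' foreground seed sits inside the frame (default: the image center). With
#' the object in a roughly fixed position this makes segmentation fully
#' automatic.
#'
#' @param rows,cols image dimensions.
#' @param margin_fraction distance of the frame from the border, as a
#'   fraction of each dimension, in (0, 0.5). Default 0.05.
#' @param thickness frame thickness in pixels (default 1).
#' @param fg foreground seed as `c(row, col)` (1-based) or `NULL` for the
#'   image center `(floor(rows/2)+1, floor(cols/2)+1)`.
#' @return a [seed_set()].
#' @export
viewfinder_seeds <- function(rows, cols, margin_fraction = 0.05,
                             thickness = 1L, fg = NULL) {
  if (!is.numeric(margin_fraction) || length(margin_fraction) != 1 ||
      margin_fraction <= 0 || margin_fraction >= 0.5) {
    ap_stop("margin_fraction must lie in (0, 0.5)", "apseg_invalid_parameter")
  }
  thickness <- as.integer(thickness)
  if (is.na(thickness) || thickness < 1) {
    ap_stop("thickness must be a positive integer", "apseg_invalid_parameter")
  }
  off_r <- max(1L, as.integer(floor(rows * margin_fraction)))
  off_c <- max(1L, as.integer(floor(cols * margin_fraction)))
  r1 <- off_r + 1L; r2 <- rows - off_r
  c1 <- off_c + 1L; c2 <- cols - off_c
  # hole = strict interior of the frame
  h_r1 <- r1 + thickness; h_r2 <- r2 - thickness
  h_c1 <- c1 + thickness; h_c2 <- c2 - thickness
  if (r2 - r1 < 2L * thickness || c2 - c1 < 2L * thickness ||
      h_r1 > h_r2 || h_c1 > h_c2) {
    ap_stop("viewfinder frame is degenerate: margin too large or image too small",
            "apseg_invalid_geometry")
  }

  ring <- function(a1, a2, b1, b2, ia1, ia2, ib1, ib2) {
    rr <- rep(a1:a2, times = b2 - b1 + 1L)
    cc <- rep(b1:b2, each = a2 - a1 + 1L)
    inside <- rr >= ia1 & rr <= ia2 & cc >= ib1 & cc <= ib2
    cbind(rr[!inside], cc[!inside])
  }
  frame <- ring(r1, r2, c1, c2, h_r1, h_r2, h_c1, h_c2)
  bg <- node_index(frame[, 1], frame[, 2], cols)

  if (is.null(fg)) fg <- c(floor(rows / 2) + 1L, floor(cols / 2) + 1L)
  if (length(fg) != 2 || anyNA(fg)) {
    ap_stop("fg must be c(row, col)", "apseg_invalid_parameter")
  }
  if (fg[1] < h_r1 || fg[1] > h_r2 || fg[2] < h_c1 || fg[2] > h_c2) {
    ap_stop("foreground seed must lie strictly inside the viewfinder frame",
            "apseg_invalid_geometry")
  }
  seed_set(node_index(fg[1], fg[2], cols), bg)
}

#' Render a seed set as a 3-value raster
#'
#' 0 = unlabeled, 1 = foreground, 2 = background.
#'
#' @param seeds a `seed_set`.
#' @param rows,cols image dimensions.
#' @return integer matrix.
#' @export
seed_raster <- function(seeds, rows, cols) {
  v <- integer(rows * cols)
  v[seeds$foreground] <- 1L
  v[seeds$background] <- 2L
  mat_rm(v, rows, cols)
}
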