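# Conversion of rasters to normalized intensity grids, plus PNG I/O.

#' Convert a raster to a normalized intensity grid
#'
#' Accepts a grayscale matrix or a 3-channel array (rows x cols x 3). Color
#' input is converted to luminance with Rec. 601 weights
#' (0.299 R + 0.587 G + 0.114 B), then the result is linearly rescaled so
#' that the minimum maps to 0 and the maximum to 1. A constant image maps to
#' all zeros. Edge weights, attraction factors and the published beta range
#' (roughly 230-340) all assume this unit intensity scale.
#'
#' @param x numeric matrix, or array with a third dimension of length 1 or 3.
#' @return numeric matrix with values in \[0, 1\].
#' @export
as_intensity_grid <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    if (d[3] == 1) {
      x <- matrix(x[, , 1], d[1], d[2])
    } else if (d[3] >= 3) {
      # silently drop an alpha channel if present
      x <- matrix(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3],
                  d[1], d[2])
    } else {
      ap_stop("raster must have 1 or 3 channels", "apseg_invalid_input")
    }
  }
  if (!is.matrix(x) || !is.numeric(x) || length(x) == 0) {
    ap_stop("raster must be a non-empty numeric matrix or rows x cols x 3 array",
            "apseg_invalid_input")
  }
  if (!all(is.finite(x))) {
    ap_stop("raster contains non-finite pixel values", "apseg_invalid_input")
  }
  if (length(x) < 2) {
    ap_stop("image must contain at least 2 pixels", "apseg_invalid_input")
  }
  rng <- range(x)
  if (rng[2] > rng[1]) {
    x <- (x - rng[1]) / (rng[2] - rng[1])
  } else {
    x[] <- 0
  }
  x
}

validate_intensity_grid <- function(grid) {
  if (!is.matrix(grid) || !is.numeric(grid) || length(grid) < 2 ||
      !all(is.finite(grid)) || min(grid) < 0 || max(grid) > 1) {
    ap_stop("intensity grid must be a numeric matrix with finite values in [0, 1] and >= 2 pixels",
            "apseg_invalid_input")
  }
  invisible(grid)
}

#' Read an image file as an intensity grid
#'
#' @param path PNG file.
#' @return result of [as_intensity_grid()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) ap_stop(paste("no such file:", path), "apseg_invalid_input")
  as_intensity_grid(png::readPNG(path))
}

#' Read a binary mask (white object on black background)
#'
#' Pixels above 0.5 after grayscale conversion are foreground.
#'
#' @param path PNG file.
#' @return binary 0/1 matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) ap_stop(paste("no such file:", path), "apseg_invalid_input")
  x <- png::readPNG(path)
  if (is.array(x) && length(dim(x)) == 3) {
    x <- if (dim(x)[3] >= 3) 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3] else x[, , 1]
  }
  (x > 0.5) + 0
}

#' Write a binary mask as a PNG (white object on black background)
#'
#' @param mask binary 0/1 matrix.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask, path)
  invisible(path)
}

#' Write a real-valued field (e.g. probabilities) as a grayscale PNG
#'
#' Values are clipped to \[0, 1\].
#'
#' @param field numeric matrix.
#' @param path output file.
#' @export
write_field <- function(field, path) {
  png::writePNG(pmin(pmax(field, 0), 1), path)
  invisible(path)
}
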