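# Synthetic phantom generator: polyp-like blobs on a textured, vignetted,
# noisy background, with optional weak-boundary gaps; plus mask corpora for
# prior training.

#' Phantom specification
#'
#' Describes one synthetic test image. The object is star-shaped with a
#' per-angle radius function R(theta): a disk (one radius), an ellipse (two
#' radii, random orientation) or a perturbed blob (low-order cosine
#' perturbations of the radius). The image is background + texture +
#' contrast inside the mask + radial vignette + Gaussian noise, clipped to
#' \[0, 1\].
#'
#' @param rows,cols image dimensions (default 96 x 96).
#' @param shape `"disk"`, `"ellipse"` or `"blob"`.
#' @param center object center `c(row, col)`; default the image center.
#' @param radii radius in pixels (disk/blob: length 1; ellipse: length 2).
#' @param contrast intensity offset of the object versus the background;
#'   negative values give depressed (dark) objects.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param vignette_strength radial brightness falloff towards the image
#'   corners (endoscope-like illumination).
#' @param gap_fraction fraction of the boundary (a contiguous angular arc)
#'   where the edge is feathered into the background — the weak-boundary
#'   case. In \[0, 1).
#' @param gap_softness half-width in pixels of the feathered ramp
#'   (default 9, which puts the ramp gradient at the noise scale so the
#'   feathered arc carries no reliable edge evidence).
#' @param background base background intensity.
#' @param texture_amp amplitude of the smooth sinusoidal background texture.
#' @param rng_seed integer seed; generation is deterministic given the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 96, cols = 96, shape = "disk", center = NULL,
                         radii = 20, contrast = 0.35, noise_sigma = 0.02,
                         vignette_strength = 0.08, gap_fraction = 0,
                         gap_softness = 9, background = 0.35,
                         texture_amp = 0.05, rng_seed = 1) {
  shape <- match.arg(shape, c("disk", "ellipse", "blob"))
  if (is.null(center)) center <- c(floor(rows / 2) + 1, floor(cols / 2) + 1)
  if (shape == "ellipse" && length(radii) == 1) radii <- c(radii, radii)
  if (any(radii <= 0) || !is.numeric(radii)) {
    ap_stop("radii must be positive", "apseg_invalid_spec")
  }
  if (gap_fraction < 0 || gap_fraction >= 1) {
    ap_stop("gap_fraction must lie in [0, 1)", "apseg_invalid_spec")
  }
  if (noise_sigma < 0 || vignette_strength < 0) {
    ap_stop("noise_sigma and vignette_strength must be nonnegative", "apseg_invalid_spec")
  }
  structure(list(rows = rows, cols = cols, shape = shape, center = center,
                 radii = radii, contrast = contrast, noise_sigma = noise_sigma,
                 vignette_strength = vignette_strength,
                 gap_fraction = gap_fraction, gap_softness = gap_softness,
                 background = background, texture_amp = texture_amp,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Per-angle radius of the three shape families. `pars` carries the random
# draws (orientation, blob perturbation) so rasterization stays deterministic.
shape_radius <- function(theta, shape, radii, pars) {
  switch(shape,
    disk = rep(radii[1], length(theta)),
    ellipse = {
      a <- radii[1]; b <- radii[2]; phi <- pars$rotation
      a * b / sqrt((b * cos(theta - phi))^2 + (a * sin(theta - phi))^2)
    },
    blob = {
      r <- rep(radii[1], length(theta))
      for (k in seq_along(pars$amps)) {
        r <- r * (1 + pars$amps[k] * cos((k + 1) * theta + pars$phases[k]))
      }
      r
    })
}

draw_shape_pars <- function(shape) {
  # consumes RNG; call inside with_seed
  switch(shape,
    disk = list(),
    ellipse = list(rotation = runif(1, 0, pi)),
    blob = list(amps = runif(3, 0.03, 0.12), phases = runif(3, 0, 2 * pi)))
}

rasterize_shape <- function(rows, cols, shape, center, radii, pars) {
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  dr <- rr - center[1]; dc <- cc - center[2]
  d <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  R <- matrix(shape_radius(as.vector(theta), shape, radii, pars), rows, cols)
  list(mask = (d <= R) + 0, signed = R - d, theta = theta)
}

#' Generate a synthetic phantom image with ground truth
#'
#' Deterministic given the spec (including its `rng_seed`). The returned
#' image is already a valid intensity grid (values in \[0, 1\]); it is not
#' re-normalized, so the stated contrast is preserved.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (intensity grid), `mask` (binary ground truth)
#'   and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    ap_stop("spec must be a phantom_spec", "apseg_invalid_spec")
  }
  rows <- spec$rows; cols <- spec$cols
  maxr <- max(spec$radii) * (if (spec$shape == "blob") 1.4 else 1)
  if (spec$center[1] - maxr < 1.5 || spec$center[1] + maxr > rows - 0.5 ||
      spec$center[2] - maxr < 1.5 || spec$center[2] + maxr > cols - 0.5) {
    ap_stop("shape exceeds the image frame", "apseg_invalid_spec")
  }
  withr::with_seed(spec$rng_seed, {
    pars <- draw_shape_pars(spec$shape)
    ras <- rasterize_shape(rows, cols, spec$shape, spec$center, spec$radii, pars)

    rr <- matrix(seq_len(rows), rows, cols)
    cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    ph <- runif(2, 0, 2 * pi)
    texture <- spec$texture_amp *
      sin(2 * pi * 2.5 * rr / rows + ph[1]) * sin(2 * pi * 2.5 * cc / cols + ph[2])

    # contrast field: hard indicator, feathered over a ramp inside the gap arc
    cfield <- ras$mask
    if (spec$gap_fraction > 0) {
      theta0 <- runif(1, -pi, pi)
      ang <- (as.vector(ras$theta) - theta0) %% (2 * pi)
      in_arc <- matrix(ang < 2 * pi * spec$gap_fraction, rows, cols)
      w <- spec$gap_softness
      ramp <- pmin(pmax((ras$signed + w) / (2 * w), 0), 1)
      cfield[in_arc] <- ramp[in_arc]
    }

    ic <- c(rows / 2 + 0.5, cols / 2 + 0.5)
    d0 <- sqrt((rr - ic[1])^2 + (cc - ic[2])^2)
    vignette <- spec$vignette_strength * (d0 / max(d0))^2

    img <- spec$background + texture + spec$contrast * cfield - vignette +
      matrix(rnorm(rows * cols, 0, spec$noise_sigma), rows, cols)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = ras$mask, spec = spec)
  })
}

#' Generate a corpus of binary object masks for prior training
#'
#' Shapes, radii, orientations and centers are randomized; reproducible from
#' the seed. Stands in for a database of expert-annotated ground-truth masks.
#'
#' @param n number of masks.
#' @param rows,cols canvas size (default 96 x 96).
#' @param radius_range range of the base radius in pixels. The default
#'   (10-24) is deliberately broader than the evaluation range of
#'   [generate_phantom_set()], mirroring a training database with more size
#'   diversity than any one test subject; it keeps the thresholded prior
#'   core a conservative subset of typical objects.
#' @param shapes shape families to sample from.
#' @param fixed_radius optional single radius overriding `radius_range`.
#' @param rng_seed integer seed.
#' @return list of `n` binary masks.
#' @export
generate_mask_corpus <- function(n, rows = 96, cols = 96,
                                 radius_range = c(10, 24),
                                 shapes = c("disk", "ellipse"),
                                 fixed_radius = NULL, rng_seed = 1) {
  if (n < 1) ap_stop("n must be >= 1", "apseg_invalid_input")
  withr::with_seed(as.integer(rng_seed), {
    lapply(seq_len(n), function(k) {
      shape <- sample(shapes, 1)
      r0 <- if (!is.null(fixed_radius)) fixed_radius else runif(1, radius_range[1], radius_range[2])
      radii <- if (shape == "ellipse") sort(runif(2, 0.8 * r0, 1.2 * r0), decreasing = TRUE) else r0
      maxr <- max(radii) * (if (shape == "blob") 1.4 else 1)
      center <- c(round(runif(1, maxr + 2, rows - maxr - 1)),
                  round(runif(1, maxr + 2, cols - maxr - 1)))
      pars <- draw_shape_pars(shape)
      rasterize_shape(rows, cols, shape, center, radii, pars)$mask
    })
  })
}

#' Generate a standard evaluation set of phantoms
#'
#' The package's reference evaluation protocol: `n` phantoms with shapes
#' sampled from disks and ellipses, base radii uniform in `radius_range`
#' (default 16-24 px on the 96 x 96 canvas, the upper part of the training
#' corpus range: the viewfinder assumption is that the operator frames an
#' object of typical size), centers jittered up to `jitter` pixels around the
#' image center (the near-fixed-position automatic mode), and otherwise the
#' [phantom_spec()] defaults. Deterministic given `rng_seed`.
#'
#' @param n number of phantoms.
#' @param gap_fraction weak-boundary arc fraction (0 for the clean set).
#' @param rng_seed integer seed.
#' @param rows,cols image dimensions.
#' @param radius_range evaluation radius range; default
#'   `c(rows/6, rows/4)` (16-24 px at the default canvas).
#' @param jitter maximum absolute center offset in pixels; default
#'   `round(rows/32)`.
#' @param noise_sigma,contrast forwarded to [phantom_spec()].
#' @return list of `n` results of [generate_phantom()].
#' @export
generate_phantom_set <- function(n, gap_fraction = 0, rng_seed = 1,
                                 rows = 96, cols = 96,
                                 radius_range = NULL, jitter = NULL,
                                 noise_sigma = 0.02, contrast = 0.35) {
  if (n < 1) ap_stop("n must be >= 1", "apseg_invalid_input")
  if (is.null(radius_range)) radius_range <- c(rows / 6, rows / 4)
  if (is.null(jitter)) jitter <- max(1, round(rows / 32))
  rng_seed <- as.integer(rng_seed)
  draws <- withr::with_seed(rng_seed, list(
    shape = sample(c("disk", "ellipse"), n, replace = TRUE),
    radius = runif(n, radius_range[1], radius_range[2]),
    jit = matrix(sample(seq(-jitter, jitter), 2 * n, replace = TRUE), n, 2)))
  ctr <- c(floor(rows / 2) + 1, floor(cols / 2) + 1)
  lapply(seq_len(n), function(k) {
    generate_phantom(phantom_spec(
      rows = rows, cols = cols, shape = draws$shape[k],
      center = ctr + draws$jit[k, ], radii = draws$radius[k],
      contrast = contrast, noise_sigma = noise_sigma,
      gap_fraction = gap_fraction,
      rng_seed = rng_seed + 1000L + k))
  })
}
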