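# Assembly and solution of the per-label sparse linear systems for the three
# attraction variants and the random-walker baseline.

AP_VARIANTS <- c("l2", "pea", "inn", "rw")

#' Evaluate the segmentation objective for one label
#'
#' Returns the attraction term plus the smoothness term,
#' sum_{i in region} D(a_i, x_i, tau_i) + sum_{ij} w_ij (x_i - x_j)^2, with D
#' the Pearson form a (x - tau)^2 / (2 tau), the inner product a x tau, or
#' the squared L2 form a (x - tau)^2. For `variant = "rw"` (or `field =
#' NULL`) only the smoothness term is returned.
#'
#' @param variant one of `"pea"`, `"inn"`, `"l2"`, `"rw"`.
#' @param x numeric vector of per-node values for the label, node order.
#' @param graph a `lattice_graph`.
#' @param field an `attraction_field` with factors, or NULL.
#' @param label `"f"` or `"b"`.
#' @param eps_tau floor for the Pearson denominator; a region node with
#'   tau = 0 and no floor is an error.
#' @return scalar objective value.
#' @export
evaluate_objective <- function(variant, x, graph, field = NULL, label = "f",
                               eps_tau = 0) {
  variant <- match.arg(variant, AP_VARIANTS)
  e <- graph$edges
  smooth <- sum(graph$weights * (x[e[, 1]] - x[e[, 2]])^2)
  if (variant == "rw" || is.null(field)) return(smooth)
  if (is.null(field$factors)) {
    ap_stop("field must have factors (see attraction_factors)", "apseg_invalid_input")
  }
  reg <- which(vec_rm(field$region))
  if (length(reg) == 0) return(smooth)
  a <- vec_rm(field$factors)[reg]
  tau <- range_base(field, label, eps_tau = eps_tau)[reg]
  xr <- x[reg]
  d <- switch(variant,
    pea = {
      if (any(tau <= 0)) {
        ap_stop("Pearson attraction term undefined: tau = 0 on a region node (set eps_tau > 0)",
                "apseg_degenerate_tau")
      }
      sum(a * (xr - tau)^2 / (2 * tau))
    },
    inn = sum(a * xr * tau),
    l2 = sum(a * (xr - tau)^2))
  d + smooth
}

#' Assemble the per-label linear systems
#'
#' Implements the published systems verbatim. With A the diagonal attraction
#' matrix restricted to unmarked nodes (A_U), tau^c the per-label range base
#' and m^c the seed indicator:
#' \itemize{
#'   \item PEA: (L_U + (1/2) A_U diag(1/tau^c)) x = -B^T m^c + diag(A_U)
#'   \item INN: L_U x = -B^T m^c + A_U tau^c
#'   \item L2:  (L_U + A_U) x = -B^T m^c + A_U tau^c
#'   \item RW:  L_U x = -B^T m^c
#' }
#' With an empty attraction region every variant collapses to the RW system.
#' The Pearson system matrix is label-dependent (it contains 1/tau^c), so one
#' matrix is assembled per label.
#'
#' @param variant one of `"pea"`, `"inn"`, `"l2"`, `"rw"`.
#' @param ops a `graph_operators`.
#' @param field an `attraction_field` with factors, or NULL for no
#'   attraction.
#' @param eps_tau floor applied to tau inside the region for the Pearson
#'   variant (default 1e-6); keeps 1/tau finite where tau^b = 0.
#' @return object of class `system_bundle`: list with `variant`, `matrix`
#'   (list `f`, `b` of sparse symmetric matrices), `rhs` (list `f`, `b`),
#'   `marked`, `unmarked`, `m`, `rows`, `cols`.
#' @export
assemble_system <- function(variant, ops, field = NULL, eps_tau = 1e-6) {
  variant <- match.arg(variant, AP_VARIANTS)
  if (!inherits(ops, "graph_operators")) {
    ap_stop("ops must be a graph_operators", "apseg_invalid_input")
  }
  U <- ops$unmarked
  aU <- if (is.null(field) || variant == "rw") {
    numeric(length(U))
  } else {
    if (is.null(field$factors)) {
      ap_stop("field must have factors (see attraction_factors)", "apseg_invalid_input")
    }
    vec_rm(field$factors)[U]
  }
  nu <- length(U)
  mats <- list(); rhss <- list()
  for (lab in c("f", "b")) {
    rhs <- as.numeric(-Matrix::t(ops$B) %*% ops$m[, lab])
    M <- ops$L_U
    if (any(aU > 0)) {
      tauU <- range_base(field, lab,
                         eps_tau = if (variant == "pea") eps_tau else 0)[U]
      if (variant == "pea") {
        d <- ifelse(aU > 0, 0.5 * aU / tauU, 0)
        M <- M + Matrix::Diagonal(nu, d)
        rhs <- rhs + aU
      } else if (variant == "inn") {
        rhs <- rhs + aU * tauU
      } else if (variant == "l2") {
        M <- M + Matrix::Diagonal(nu, aU)
        rhs <- rhs + aU * tauU
      }
    }
    mats[[lab]] <- Matrix::forceSymmetric(M)
    rhss[[lab]] <- rhs
  }
  structure(list(variant = variant, matrix = mats, rhs = rhss,
                 marked = ops$marked, unmarked = U, m = ops$m,
                 rows = ops$rows, cols = ops$cols),
            class = "system_bundle")
}

# Jacobi-preconditioned conjugate gradient fallback for symmetric positive
# definite sparse systems (the Laplacian diagonals span many orders of
# magnitude at large beta, so plain CG stalls).
cg_solve <- function(M, b, tol = 1e-10, maxit = NULL) {
  n <- length(b)
  if (is.null(maxit)) maxit <- 10L * n
  dinv <- 1 / Matrix::diag(M)
  x <- numeric(n)
  r <- b - as.numeric(M %*% x)
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  bn <- 1 + sqrt(sum(b * b))
  for (k in seq_len(maxit)) {
    Mp <- as.numeric(M %*% p)
    alpha <- rz / sum(p * Mp)
    x <- x + alpha * p
    r <- r - alpha * Mp
    if (sqrt(sum(r * r)) <= tol * bn) return(x)
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}

#' Solve the per-label systems into a probability field
#'
#' One sparse symmetric solve per label (direct factorization, with a
#' conjugate-gradient fallback). Marked nodes are fixed to their seed
#' indicators; unmarked solutions are scattered back to image (node) order.
#' The residual must satisfy ||Mx - b||_inf <= 1e-8 (1 + ||b||_inf).
#'
#' @param bundle a `system_bundle`.
#' @return object of class `ap_probabilities`: list with `x` (n x 2 matrix,
#'   columns `f`, `b`), `rows`, `cols`, `variant`.
#' @export
solve_probabilities <- function(bundle) {
  if (!inherits(bundle, "system_bundle")) {
    ap_stop("bundle must be a system_bundle", "apseg_invalid_input")
  }
  n <- bundle$rows * bundle$cols
  x <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("f", "b")))
  x[bundle$marked, ] <- bundle$m
  for (lab in c("f", "b")) {
    M <- bundle$matrix[[lab]]; b <- bundle$rhs[[lab]]
    if (length(b) == 0) next
    xu <- tryCatch(as.numeric(Matrix::solve(M, b)),
                   error = function(e) cg_solve(M, b))
    res <- max(abs(as.numeric(M %*% xu) - b))
    if (res > 1e-12 * (1 + max(abs(b)))) {
      # one step of iterative refinement tightens ill-conditioned solves
      xu <- xu + as.numeric(Matrix::solve(M, b - as.numeric(M %*% xu)))
      res <- max(abs(as.numeric(M %*% xu) - b))
    }
    tol <- 1e-8 * (1 + max(abs(b)))
    if (!is.finite(res) || res > tol) {
      xu <- cg_solve(M, b)
      res <- max(abs(as.numeric(M %*% xu) - b))
      if (!is.finite(res) || res > tol) {
        ap_stop(sprintf(
          "linear solve failed for label %s: residual %.3e exceeds %.3e (disconnected unseeded component with epsilon_w = 0?)",
          lab, res, tol), "apseg_solver_error")
      }
    }
    x[bundle$unmarked, lab] <- xu
  }
  structure(list(x = x, rows = bundle$rows, cols = bundle$cols,
                 variant = bundle$variant),
            class = "ap_probabilities")
}

#' Assign labels from a probability field
#'
#' Foreground where x^f > x^b; ties go to foreground (favors recall). Seeded
#' pixels keep their labels (their probabilities are fixed indicators).
#'
#' @param prob an `ap_probabilities`.
#' @return binary 0/1 matrix.
#' @export
assign_labels <- function(prob) {
  if (!inherits(prob, "ap_probabilities")) {
    ap_stop("prob must be an ap_probabilities", "apseg_invalid_input")
  }
  mat_rm(as.numeric(prob$x[, "f"] >= prob$x[, "b"]), prob$rows, prob$cols)
}

#' Segment an image with attraction propagation
#'
#' Full pipeline: lattice graph, Laplacian blocks, prior placement at the
#' (single) foreground seed, attraction factors and range bases, per-label
#' sparse solves, and label assignment. With `prior = NULL` or
#' `variant = "rw"` the attraction term vanishes and the result is the plain
#' random-walker segmentation.
#'
#' @param grid intensity grid (see [as_intensity_grid()]).
#' @param seeds a [seed_set()]; exactly one foreground seed when a prior is
#'   supplied.
#' @param prior a `shape_prior`, or NULL.
#' @param variant `"l2"` (default), `"pea"`, `"inn"` or `"rw"`.
#' @param beta edge-weight contrast parameter (default 310, the published
#'   operating point for PEA/L2).
#' @param gamma optional re-threshold of the prior before placement.
#' @param connectivity 4 or 8.
#' @param epsilon_w additive edge-weight floor.
#' @param eps_tau Pearson tau floor.
#' @param sharpness attraction-factor sharpness multiplier.
#' @return object of class `ap_segmentation`: list with `mask`,
#'   `probabilities` (an `ap_probabilities`), and a provenance record
#'   (`variant`, `beta`, `gamma`, `connectivity`, `epsilon_w`, `eps_tau`,
#'   `sharpness`, `seeds`).
#' @export
ap_segment <- function(grid, seeds, prior = NULL, variant = "l2",
                       beta = 310, gamma = NULL, connectivity = 4,
                       epsilon_w = 1e-6, eps_tau = 1e-6, sharpness = 1) {
  variant <- match.arg(variant, AP_VARIANTS)
  validate_intensity_grid(grid)
  if (!inherits(seeds, "seed_set")) {
    ap_stop("seeds must be a seed_set", "apseg_invalid_seed")
  }
  graph <- build_lattice_graph(grid, beta = beta, connectivity = connectivity,
                               epsilon_w = epsilon_w)
  ops <- graph_operators(graph, seeds)
  field <- NULL
  if (!is.null(prior) && variant != "rw") {
    if (length(seeds$foreground) != 1) {
      ap_stop("attraction propagation uses exactly one foreground seed",
              "apseg_invalid_seed")
    }
    if (!is.null(gamma)) prior <- threshold_prior(prior, gamma)
    if (is.null(prior$threshold_matrix)) {
      ap_stop("prior has no threshold matrix: supply gamma or call threshold_prior",
              "apseg_invalid_input")
    }
    if (any(prior$threshold_matrix > 0)) {
      fg_rc <- node_rc(seeds$foreground, ncol(grid))
      field <- place_prior(prior, c(fg_rc[1, 1], fg_rc[1, 2]), grid)
      field <- attraction_factors(field, grid, sharpness = sharpness)
    }  # empty prior support: attraction vanishes, plain random walker
  }
  bundle <- assemble_system(variant, ops, field, eps_tau = eps_tau)
  prob <- solve_probabilities(bundle)
  structure(list(mask = assign_labels(prob), probabilities = prob,
                 variant = variant, beta = beta,
                 gamma = if (!is.null(field)) prior$gamma else NULL,
                 connectivity = connectivity, epsilon_w = epsilon_w,
                 eps_tau = eps_tau, sharpness = sharpness, seeds = seeds),
            class = "ap_segmentation")
}
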