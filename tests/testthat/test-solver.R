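test_that("objective evaluation matches scalar arithmetic on the three forms", {
  mi <- micro_instance()
  # single region node, a = 1, tau^f = 0.8, x at the unknown = 0.6;
  # seeds at x^f = (1, 0) contribute smoothness (1-0.6)^2 + (0.6-0)^2 = 0.52
  x <- c(1, 0.6, 0)
  smooth <- 0.4^2 + 0.6^2
  expect_equal(evaluate_objective("l2", x, mi$graph, mi$field, "f"),
               0.04 + smooth, tolerance = 1e-12)
  expect_equal(evaluate_objective("pea", x, mi$graph, mi$field, "f"),
               0.025 + smooth, tolerance = 1e-12)
  expect_equal(evaluate_objective("inn", x, mi$graph, mi$field, "f"),
               0.48 + smooth, tolerance = 1e-12)
  expect_equal(evaluate_objective("rw", x, mi$graph, NULL, "f"), smooth)
  # x = tau on the region of a constant field: L2/Pearson attraction vanish
  xt <- c(0.8, 0.8, 0.8)
  expect_equal(evaluate_objective("l2", xt, mi$graph, mi$field, "f"), 0)
  expect_equal(evaluate_objective("pea", xt, mi$graph, mi$field, "f"), 0)
  # two-node graph with w = 0.5 and x = (1, 0): smoothness 0.5
  g2 <- build_lattice_graph(matrix(c(0.3, 0.3 + log(2) / 100), 1, 2),
                            beta = 100, epsilon_w = 0)
  expect_equal(evaluate_objective("rw", c(1, 0), g2, NULL, "f"), 0.5,
               tolerance = 1e-12)
  # Pearson with tau = 0 at a region node and no floor is degenerate
  fb <- mi$field; fb$shifted_t[1, 2] <- 1  # tau^b = 0 there
  expect_error(evaluate_objective("pea", x, mi$graph, fb, "b", eps_tau = 0),
               class = "apseg_degenerate_tau")
})

test_that("system assembly reproduces the hand-built micro systems", {
  mi <- micro_instance()
  # L2: (2 + 1) x = 1 + 0.8
  bl2 <- assemble_system("l2", mi$ops, mi$field)
  expect_equal(as.matrix(bl2$matrix$f), matrix(3), tolerance = 1e-12)
  expect_equal(bl2$rhs$f, 1.8, tolerance = 1e-12)
  # PEA, label f: (2 + 0.5/0.8) x = 1 + 1
  bp <- assemble_system("pea", mi$ops, mi$field)
  expect_equal(as.matrix(bp$matrix$f), matrix(2.625), tolerance = 1e-12)
  expect_equal(bp$rhs$f, 2, tolerance = 1e-12)
  # PEA, label b: (2 + 0.5/0.2) x = 1 + 1
  expect_equal(as.matrix(bp$matrix$b), matrix(4.5), tolerance = 1e-12)
  expect_equal(bp$rhs$b, 2, tolerance = 1e-12)
  # INN: 2 x = 1 + 0.8
  bi <- assemble_system("inn", mi$ops, mi$field)
  expect_equal(as.matrix(bi$matrix$f), matrix(2), tolerance = 1e-12)
  expect_equal(bi$rhs$f, 1.8, tolerance = 1e-12)
  # empty region: every variant degenerates to the RW system
  ef <- empty_field(mi$field)
  for (v in c("pea", "inn", "l2")) {
    b <- assemble_system(v, mi$ops, ef)
    expect_equal(as.matrix(b$matrix$f), matrix(2), tolerance = 1e-12)
    expect_equal(b$rhs$f, 1, tolerance = 1e-12)
  }
})

test_that("micro-example solves give the hand-derived probabilities", {
  mi <- micro_instance()
  sol <- function(v) solve_probabilities(assemble_system(v, mi$ops, mi$field))$x[2, ]
  expect_equal(unname(sol("l2")), c(0.6, 0.4), tolerance = 1e-10)
  expect_equal(unname(sol("pea")), c(2 / 2.625, 2 / 4.5), tolerance = 1e-10)
  expect_equal(unname(sol("inn")), c(0.9, 0.6), tolerance = 1e-10)
  x_rw <- solve_probabilities(assemble_system("rw", mi$ops, NULL))$x
  expect_equal(unname(x_rw[2, ]), c(0.5, 0.5), tolerance = 1e-10)
  # marked nodes keep their indicators exactly
  expect_identical(unname(x_rw[1, ]), c(1, 0))
  expect_identical(unname(x_rw[3, ]), c(0, 1))
})

test_that("label assignment uses the foreground tie rule and fixed seeds", {
  p <- structure(list(x = cbind(f = c(1, 0.6, 0.5, 0.2, 0),
                                b = c(0, 0.4, 0.5, 0.8, 1)),
                      rows = 1L, cols = 5L, variant = "l2"),
                 class = "ap_probabilities")
  expect_equal(as.vector(assign_labels(p)), c(1, 1, 1, 0, 0))
})

test_that("segment with no prior, empty support, or gamma = 1 reduces to RW", {
  grid <- random_grid(12, 12, 61)
  seeds <- viewfinder_seeds(12, 12, margin_fraction = 0.09)
  ref <- ap_segment(grid, seeds, prior = NULL, variant = "rw", beta = 120)
  no_prior <- ap_segment(grid, seeds, prior = NULL, variant = "l2", beta = 120)
  expect_identical(no_prior$mask, ref$mask)
  expect_equal(no_prior$probabilities$x, ref$probabilities$x, tolerance = 1e-12)
  # all SP < 1 and gamma = 1: empty support, attraction vanishes
  corpus <- generate_mask_corpus(3, rows = 12, cols = 12, radius_range = c(2, 3),
                                 rng_seed = 9)
  prior <- train_shape_prior(corpus, gamma = 0.8)
  if (any(prior$sp == 1)) prior$counts[prior$counts == 3] <- 2  # force SP < 1
  prior <- apseg:::new_shape_prior(prior$counts, prior$n_samples, gamma = 0.8)
  g1 <- ap_segment(grid, seeds, prior = prior, variant = "l2", beta = 120, gamma = 1)
  expect_identical(g1$mask, ref$mask)
})

test_that("attraction strength moves the solution monotonically toward tau", {
  grid <- matrix(0, 10, 10)
  seeds <- viewfinder_seeds(10, 10, margin_fraction = 0.1)
  ops <- graph_operators(build_lattice_graph(grid, beta = 310), seeds)
  prior <- threshold_prior(shape_probability(list(matrix(1, 5, 5))), 0.5)
  field <- attraction_factors(place_prior(prior, c(6, 6), grid), grid)
  reg <- setdiff(which(apseg:::vec_rm(field$region)), seeds$marked)
  scales <- c(0, 0.25, 0.5, 0.75, 1)
  xf <- sapply(scales, function(t) {
    ft <- field; ft$factors <- field$factors * t
    mean(solve_probabilities(assemble_system("l2", ops, ft))$x[reg, "f"])
  })
  expect_true(all(diff(xf) > 0))          # monotone from the RW value ...
  expect_lt(max(xf), 1)                   # ... toward the tau-driven value (= 1 here)
  x_rw <- mean(solve_probabilities(assemble_system("rw", ops, NULL))$x[reg, "f"])
  expect_equal(xf[1], x_rw, tolerance = 1e-12)
})

test_that("segmentation is deterministic and records provenance", {
  ph <- generate_phantom(phantom_spec(rows = 48, cols = 48, radii = 9, rng_seed = 3))
  seeds <- viewfinder_seeds(48, 48)
  prior <- train_shape_prior(generate_mask_corpus(10, rows = 48, cols = 48,
                                                  radius_range = c(5, 11),
                                                  rng_seed = 4), gamma = 0.8)
  s1 <- ap_segment(ph$image, seeds, prior, variant = "l2")
  s2 <- ap_segment(ph$image, seeds, prior, variant = "l2")
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$probabilities$x, s2$probabilities$x)
  expect_equal(s1$variant, "l2")
  expect_equal(s1$beta, 310)
  expect_equal(s1$gamma, 0.8)
  # multiple foreground seeds are rejected when a prior drives attraction
  multi <- seed_set(node_index(c(25L, 25L), c(25L, 26L), 48L), seeds$background)
  expect_error(ap_segment(ph$image, multi, prior, variant = "l2"),
               class = "apseg_invalid_seed")
})

test_that("conjugate-gradient fallback solves the same systems as the factorization", {
  grid <- random_grid(8, 8, 71)
  seeds <- random_seeds(64, 2, 6, 72)
  ops <- graph_operators(build_lattice_graph(grid, beta = 90, epsilon_w = 1e-3), seeds)
  b <- assemble_system("l2", ops, random_field(grid, 73))
  direct <- as.numeric(Matrix::solve(b$matrix$f, b$rhs$f))
  cg <- apseg:::cg_solve(b$matrix$f, b$rhs$f)
  expect_equal(cg, direct, tolerance = 1e-8)
})
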