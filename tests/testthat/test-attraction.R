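# A 5x5 single-mask prior: threshold support is the full 5x5 canvas.
toy_prior <- function() {
  threshold_prior(shape_probability(list(matrix(1, 5, 5))), 0.5)
}

test_that("prior placement centers the support on the seed and clips at borders", {
  grid <- matrix(0.5, 11, 11); grid[1, 1] <- 0  # non-constant, valid grid
  prior <- toy_prior()
  f <- place_prior(prior, c(6, 6), grid)
  expect_equal(which(f$region, arr.ind = TRUE)[, "row"] |> range(), c(4, 8))
  expect_equal(which(f$region, arr.ind = TRUE)[, "col"] |> range(), c(4, 8))
  # corner seed: only the bottom-right quadrant of the support survives
  fc <- place_prior(prior, c(1, 1), grid)
  expect_equal(sum(fc$region), 3 * 3)  # canvas center (3,3): cells (3:5, 3:5) remain
  expect_true(all(which(fc$region, arr.ind = TRUE) <= 3))
  # translation equivariance away from borders
  fa <- place_prior(prior, c(4, 5), grid)
  fb <- place_prior(prior, c(6, 8), grid)
  expect_identical(fa$shifted_t[2:6, 3:7], fb$shifted_t[4:8, 6:10])
  expect_error(place_prior(prior, c(0, 5), grid), class = "apseg_invalid_seed")
  half <- threshold_prior(shape_probability(list(matrix(1, 5, 5), matrix(0, 5, 5))), 0.9)
  expect_error(place_prior(half, c(6, 6), grid), class = "apseg_empty_prior")
})

test_that("placement clipping stays in bounds for fuzzed seeds including corners", {
  grid <- matrix(seq(0, 1, length.out = 63), 7, 9)
  prior <- toy_prior()
  corners <- list(c(1, 1), c(1, 9), c(7, 1), c(7, 9))
  fuzz <- withr::with_seed(21, replicate(1000, c(sample(7, 1), sample(9, 1)),
                                         simplify = FALSE))
  for (s in c(corners, fuzz)) {
    f <- place_prior(prior, s, grid)
    expect_identical(dim(f$region), c(7L, 9L))
    expect_true(sum(f$region) >= 1)
  }
})

test_that("attraction factors follow exp(-|g_i - g_s|) on the region", {
  grid <- matrix(0.2, 5, 5)
  grid[1, ] <- 1; grid[5, 5] <- 0.2  # seed row differs
  prior <- toy_prior()
  f <- attraction_factors(place_prior(prior, c(3, 3), grid), grid)
  expect_equal(f$factors[3, 3], 1)                       # g_i = g_s
  expect_equal(f$factors[1, 3], exp(-0.8), tolerance = 1e-12)
  # constant image: all factors 1 on the region
  const <- matrix(0, 4, 4)
  fc <- attraction_factors(place_prior(toy_prior(), c(2, 2), const), const)
  expect_true(all(fc$factors[fc$region] == 1))
  expect_true(all(fc$factors[!fc$region] == 0))
  # unit-range extreme: |g_i - g_s| = 1 gives exp(-1)
  ext <- matrix(0, 3, 3); ext[1, 1] <- 1
  fe <- attraction_factors(place_prior(toy_prior(), c(1, 1), ext), ext)
  expect_equal(min(fe$factors[fe$region]), exp(-1), tolerance = 1e-12)
})

test_that("range bases satisfy the per-label identities and zero pattern", {
  grid <- matrix(c(0, rep(0.5, 48)), 7, 7)
  withr::with_seed(31, {
    masks <- lapply(1:4, function(k) matrix(rbinom(25, 1, 0.6), 5, 5))
  })
  masks[[1]][3, 3] <- 1  # ensure nonempty support at gamma 0.5
  prior <- train_shape_prior(masks, gamma = 0.5)
  f <- attraction_factors(place_prior(prior, c(4, 4), grid), grid)
  tf <- range_base(f, "f"); tb <- range_base(f, "b")
  reg <- apseg:::vec_rm(f$region)
  expect_true(all(tf[!reg] == 0) && all(tb[!reg] == 0))
  expect_equal(tf[reg] + tb[reg], rep(1, sum(reg)))
  expect_equal(tf[reg], apseg:::vec_rm(f$shifted_t)[reg])
  expect_true(all(tf[reg] >= prior$gamma & tf[reg] <= 1))
  # eps_tau floor applies only inside the region
  tbf <- range_base(f, "b", eps_tau = 1e-6)
  expect_true(all(tbf[reg] >= 1e-6))
  expect_true(all(tbf[!reg] == 0))
  expect_error(range_base(f, "x"), class = "apseg_invalid_label")
  # zero-pattern consistency across factors and bases
  fac <- apseg:::vec_rm(f$factors)
  expect_identical(fac > 0, reg)
  expect_identical(tf > 0, reg)
})

test_that("attraction matrix is diagonal with the factors as entries", {
  grid <- matrix(c(0, rep(0.3, 35)), 6, 6)
  f <- attraction_factors(place_prior(toy_prior(), c(3, 4), grid), grid)
  A <- attraction_matrix(f)
  expect_equal(dim(A), c(36, 36))
  expect_equal(sum(Matrix::diag(A)), sum(f$factors), tolerance = 1e-12)
  expect_equal(Matrix::nnzero(A - Matrix::Diagonal(36, Matrix::diag(A))), 0)
  # single-node region
  one <- toy_prior(); one$threshold_matrix[] <- 0; one$threshold_matrix[3, 3] <- 1
  f1 <- attraction_factors(place_prior(one, c(2, 2), grid), grid)
  A1 <- attraction_matrix(f1)
  expect_equal(sum(A1 != 0), 1)
  expect_equal(A1[node_index(2, 2, 6), node_index(2, 2, 6)],
               exp(-abs(grid[2, 2] - grid[2, 2])))
})

test_that("attraction boosts foreground and depresses background on the region", {
  grid <- matrix(0, 9, 9)
  seeds <- viewfinder_seeds(9, 9, margin_fraction = 0.12)
  graph <- build_lattice_graph(grid, beta = 310)
  ops <- graph_operators(graph, seeds)
  prior <- toy_prior()
  field <- attraction_factors(place_prior(prior, c(5, 5), grid), grid)
  x_ap <- solve_probabilities(assemble_system("l2", ops, field))$x
  x_rw <- solve_probabilities(assemble_system("rw", ops, NULL))$x
  reg <- setdiff(which(apseg:::vec_rm(field$region)), seeds$marked)
  expect_true(all(x_ap[reg, "f"] > x_rw[reg, "f"]))
  expect_true(all(x_ap[reg, "b"] < x_rw[reg, "b"]))
})
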