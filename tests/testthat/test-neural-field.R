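test_that("sigmoid has the stated gain and antisymmetry", {
  q <- named_params("q_MC")
  expect_equal(sigmoid(0, q), 0.5)
  h <- 1e-6
  expect_equal(4 * (sigmoid(h, q) - sigmoid(-h, q)) / (2 * h), q$gamma,
               tolerance = 1e-8)
  set.seed(3)
  x <- rnorm(50, sd = 5)
  expect_equal(sigmoid(x, q) + sigmoid(-x, q), rep(1, 50))
  # saturates without overflow
  expect_equal(sigmoid(1e4, q), 1)
  expect_equal(sigmoid(-1e4, q), 0)
})

test_that("spatial DOG kernel matches its closed form", {
  q <- named_params("q_MC")
  expect_equal(spatial_kernel(c(0, 0), q), 2.60)
  expect_lt(abs(spatial_kernel(c(200, 0), q)), 1e-15)
  # exactly one sign change along a ray when alpha < beta and mu > nu
  r <- seq(0.01, 30, by = 0.01)
  vals <- spatial_kernel(cbind(r, 0), q)
  expect_equal(sum(diff(sign(vals)) != 0), 1)
  # against a literal evaluation at an arbitrary offset
  rr <- c(0.4, -0.3)
  expect_equal(spatial_kernel(rr, q),
               4.42 * exp(-0.25 / (2 * 0.58^2)) -
                 1.82 * exp(-0.25 / (2 * 8.35^2)))
})

test_that("color kernel is symmetric with Gaussians at c and -c", {
  q <- named_params("q_MC")
  expect_equal(color_kernel(0, 0, q), -0.09)
  # at (1, 1) the opponent Gaussian sits at distance 2 and is negligible
  expect_equal(color_kernel(1, 1, q),
               0.60 - 0.69 * exp(-4 / (2 * 0.40^2)))
  expect_lt(abs(color_kernel(1, 1, q) - 0.60), 1e-4)
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(color_kernel(a, b, q), color_kernel(b, a, q))
  }
  expect_error(color_kernel(c(1, 0), 0.5, q), "dimension mismatch")
})

test_that("the input lifting peaks at the viewed color", {
  q <- named_params("q_nonlin")
  expect_equal(input_kernel(0, q), 0.47)
  grid <- tiny_grid_1d(nc = 9)
  spec <- striped_pattern(0.5, 1, -1, stripe_width = 1, n_pairs = 1,
                          background_color = -0.5)
  img <- make_striped_image(spec, grid)
  H <- build_input(img, q)
  for (ix in seq_len(grid$nx)) {
    peak <- which.max(H$values[ix, 1, ])
    expect_equal(grid$cnodes[peak],
                 grid$cnodes[which.min(abs(grid$cnodes - img$values[ix, 1, 1]))])
  }
  # image color on a grid node: input reaches mu_h exactly there
  expect_equal(max(H$values), q$mu_h)
  # constant image: input independent of position
  uni <- cortical_image(array(0.5, dim = c(grid$nx, grid$ny, 1)), grid)
  Hu <- build_input(uni, q)$values
  expect_equal(max(apply(Hu, 3, function(s) diff(range(s)))), 0)
})

test_that("FFT connectivity equals the dense double sum", {
  set.seed(21)
  q <- random_params()
  for (grid in list(tiny_grid_1d(), tiny_grid_1d(boundary = "periodic"),
                    tiny_grid_2d())) {
    a <- random_activity(grid)
    expect_equal(apply_connectivity(a, q, grid, method = "fft"),
                 apply_connectivity(a, q, grid, method = "direct"),
                 tolerance = 1e-12)
  }
  # linearity: zero in, zero out
  g <- tiny_grid_1d()
  z <- array(0, dim = field_dim_for(g))
  expect_equal(apply_connectivity(z, q, g), z)
})

test_that("connectivity commutes with the color-opponency reflection", {
  set.seed(22)
  q <- random_params()
  for (grid in list(tiny_grid_1d(), tiny_grid_2d())) {
    a <- random_activity(grid)
    lhs <- apply_connectivity(sym_flip_for(a, grid), q, grid)
    rhs <- sym_flip_for(apply_connectivity(a, q, grid), grid)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("Euler steps reduce to the fixed-point map at dt = 1", {
  q <- named_params("q_MC")
  grid <- tiny_grid_1d()
  spec <- striped_pattern(0, 1, -0.84, stripe_width = 1, n_pairs = 1)
  img <- make_striped_image(spec, grid)
  set.seed(9)
  a0 <- random_activity(grid)
  one <- evolve(img, q, a0 = a0, dt = 1, n_steps = 1)
  H <- build_input(img, q)$values
  expect_equal(one$values,
               sigmoid(apply_connectivity(a0, q, grid) + H, q))
  # halving dt for twice the steps reaches the same fixed point
  s1 <- evolve(img, q, a0 = a0, dt = 1, n_steps = 160)
  s2 <- evolve(img, q, a0 = a0, dt = 0.5, n_steps = 320)
  expect_lt(max(abs(s1$values - s2$values)), 1e-4)
  expect_error(evolve(img, q, a0 = a0, dt = 1.5, n_steps = 1), "dt")
  expect_error(evolve(img, q, a0 = a0 * 0, n_steps = 1), "strictly in")
})

test_that("iterates stay strictly inside (0, 1) for random valid parameters", {
  set.seed(31)
  grid <- tiny_grid_1d(nc = 9)
  spec <- striped_pattern(0, 1, -0.84, stripe_width = 1, n_pairs = 1)
  img <- make_striped_image(spec, grid)
  for (rep in 1:5) {
    q <- random_params()
    traj <- evolve(img, q, n_steps = 12, keep_trajectory = TRUE)
    for (a in attr(traj, "trajectory")) {
      expect_true(all(a > 0 & a < 1))
    }
  }
})

test_that("steady states satisfy the fixed-point residual and are unique", {
  q <- named_params("q_MC")
  grid <- small_match_grid()
  img <- make_striped_image(small_patterns()[["6"]], grid)
  ss <- steady_state(img, q, tol = 1e-5)
  expect_true(ss$converged)
  H <- build_input(img, q)$values
  resid <- max(abs(ss$values -
                     sigmoid(apply_connectivity(ss$values, q, grid) + H, q)))
  expect_lt(resid, 1e-5)
  # random restarts land on the same state
  set.seed(41)
  for (rep in 1:3) {
    a0 <- random_activity(grid)
    ss2 <- steady_state(img, q, tol = 1e-5, a0 = a0)
    expect_true(ss2$converged)
    expect_lt(max(abs(ss2$values - ss$values)), 10 * 1e-5)
  }
  # non-convergence is flagged loudly
  expect_warning(steady_state(img, q, tol = 1e-12, max_iter = 2),
                 "did not converge")
})

test_that("steady states are equivariant under color flip and translation", {
  q <- named_params("q_MC")
  grid <- small_match_grid()
  img <- make_striped_image(small_patterns(0.4)[["6"]], grid)
  s_pos <- steady_state(img, q, tol = 1e-6)
  s_neg <- steady_state(negate_image(img), q, tol = 1e-6)
  expect_equal(s_neg$values, sym_flip_for(s_pos$values, grid),
               tolerance = 1e-6)
  # periodic domain: shifting the stimulus shifts the steady state exactly
  gp <- domain_grid(16, 4, 0.1, color_dim = 1, nc = 9,
                    boundary = "periodic")
  set.seed(13)
  vals <- array(runif(16 * 4, -1, 1), dim = c(16, 4, 1))
  base <- steady_state(cortical_image(vals, gp), q, tol = 1e-8)
  k <- 5
  shifted <- steady_state(
    cortical_image(vals[c((16 - k + 1):16, 1:(16 - k)), , , drop = FALSE], gp),
    q, tol = 1e-8)
  expect_equal(shifted$values[c((k + 1):16, 1:k), , ],
               base$values, tolerance = 1e-10)
})

test_that("color sensations slice the converged field at a hypercolumn", {
  # gentle lateral weights: the coarse 0.3-spacing grid carries large cell
  # measures, so the published amplitudes would leave the contractive regime
  q <- model_params(0.6, 0.69, 0.3, 0.4, 2.0, 0.5, 0.3, 1.0, 0.47, 0.3, 1.8)
  grid <- tiny_grid_1d(nx = 10, ny = 6, nc = 9)
  uni <- cortical_image(array(0.3, dim = c(10, 6, 1)), grid)
  ss <- steady_state(uni, q, tol = 1e-6)
  bulk <- color_sensation(ss, r0 = c(5, 3))
  expect_true(all(bulk$values > 0 & bulk$values < 1))
  neighbor <- color_sensation(ss, r0 = c(6, 3))
  expect_equal(bulk$values, neighbor$values, tolerance = 5e-3)
  expect_warning(
    color_sensation(suppressWarnings(steady_state(uni, q, tol = 1e-12,
                                                  max_iter = 2))),
    "non-converged")
})

test_that("stronger input drive does not reduce stimulated activity", {
  grid <- tiny_grid_1d(nc = 9)
  uni <- cortical_image(array(0.5, dim = c(grid$nx, grid$ny, 1)), grid)
  node <- which.min(abs(grid$cnodes - 0.5))
  ctr <- c(3, 3)
  prev <- -Inf
  for (mh in c(0.2, 0.5, 0.9)) {
    q <- model_params(0.6, 0.69, 0.3, 0.4, 4.42, 1.82, 0.58, 8.35,
                      mu_h = mh, sigma_h = 0.3, gamma = 1.8)
    ss <- steady_state(uni, q, tol = 1e-6)
    val <- ss$values[ctr[1], ctr[2], node]
    expect_gte(val, prev)
    prev <- val
  }
})
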