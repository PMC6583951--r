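test_that("sensation distance is the sup norm over color nodes", {
  q <- named_params("q_MC")
  grid <- small_match_grid()
  img <- make_striped_image(small_patterns()[["6"]], grid)
  ss <- steady_state(img, q)
  a <- color_sensation(ss)
  b <- color_sensation(ss, r0 = c(3, 2))
  expect_equal(sensation_distance(a, a), 0)
  expect_equal(sensation_distance(a, b), sensation_distance(b, a))
  expect_equal(sensation_distance(a, b), max(abs(a$values - b$values)))
  # triangle inequality on perturbed copies
  set.seed(17)
  for (i in 1:10) {
    x <- a; y <- a; z <- a
    x$values <- pmin(pmax(a$values + runif(21, -0.2, 0.2), 0.01), 0.99)
    y$values <- pmin(pmax(a$values + runif(21, -0.2, 0.2), 0.01), 0.99)
    z$values <- pmin(pmax(a$values + runif(21, -0.2, 0.2), 0.01), 0.99)
    expect_lte(sensation_distance(x, z),
               sensation_distance(x, y) + sensation_distance(y, z) + 1e-12)
  }
  # constant profiles: distance is the plain absolute difference
  p <- a; p$values <- rep(0.4, length(a$values))
  r <- a; r$values <- rep(0.65, length(a$values))
  expect_equal(sensation_distance(p, r), 0.25)
  other <- suppressWarnings(color_sensation(
    steady_state(make_striped_image(small_patterns()[["6"]],
                                    tiny_grid_1d(nx = 24, ny = 4, nc = 5)),
                 q, max_iter = 5)))
  expect_error(sensation_distance(a, other), "different color grids")
})

test_that("a test whose family contains it is matched with zero shift", {
  q <- named_params("q_MC")
  grid <- small_match_grid()
  # comparison geometry identical to the test image: surround already neutral
  pat <- striped_pattern(0.4, 0, 0, stripe_width = 2, n_pairs = 2)
  trial <- matching_trial(pat, 0.4, id = "self")
  res <- match_color(trial, q, grid, cheap_search())
  # 0.4 is on the 21-point lattice over [-2, 2]
  expect_equal(res$c_pred, 0.4, tolerance = 1e-4)
  expect_lt(abs(res$shift), 1e-4)
  expect_equal(min(res$distance_profile$dist), 0, tolerance = 1e-12)
})

test_that("SoftMin at vanishing temperature reduces to the hard argmin", {
  q <- named_params("q_MC")
  grid <- small_match_grid()
  trial <- matching_trial(small_patterns()[["6"]], 0, id = "6")
  hard <- match_color(trial, q, grid, cheap_search(temperature = 0))
  cold <- match_color(trial, q, grid, cheap_search(temperature = 1e-8))
  expect_equal(hard$c_pred, cold$c_pred, tolerance = 1e-9)
  expect_equal(hard$c_pred, hard$coarse_best)
})

test_that("matching flips sign under global color inversion", {
  q <- named_params("q_MC")
  grid <- small_match_grid()
  pats <- small_patterns()
  for (id in c("6", "2")) {
    p <- pats[[id]]
    pneg <- striped_pattern(-p$center_color, -p$adjacent_color,
                            -p$second_color, p$stripe_width, p$n_pairs,
                            -p$background_color)
    r1 <- match_color(matching_trial(p, 0.2), q, grid, cheap_search())
    r2 <- match_color(matching_trial(pneg, -0.2), q, grid, cheap_search())
    expect_equal(r2$shift, -r1$shift, tolerance = 1e-6)
  }
})

test_that("refining the candidate lattice moves the match below one cell", {
  q <- named_params("q_MC")
  grid <- small_match_grid()
  trial <- matching_trial(small_patterns()[["6"]], 0, id = "6")
  coarse <- match_color(trial, q, grid, cheap_search())          # 21 points
  fine <- match_color(trial, q, grid,
                      search_config(n_candidates = 41, refine = FALSE))
  sp <- 4 / 20
  expect_lt(abs(coarse$c_pred - fine$c_pred), sp)
  refined <- match_color(trial, q, grid,
                         search_config(n_candidates = 21, refine = 1))
  expect_lt(abs(refined$c_pred - fine$c_pred), sp)
})

test_that("the eight-pattern experiment reproduces the synergy ordering", {
  q <- named_params("q_MC")
  grid <- small_match_grid()
  tab <- ms_shift_experiment(q, c_test = 0, grid = grid,
                             search = search_config(refine = 1),
                             stripe_width = 2, n_pairs = 2)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$id, as.character(0:7))
  expect_true(all(tab$converged))
  sh <- tab$shift_1
  names(sh) <- tab$id
  # purple-adjacent patterns shift positive, lime-adjacent negative
  expect_gt(sh[["0"]], 0)
  expect_lt(sh[["1"]], 0)
  expect_gt(sh[["2"]], 0)
  expect_lt(sh[["3"]], 0)
  expect_gt(sh[["6"]], 0)
  expect_lt(sh[["7"]], 0)
})

test_that("comparison caching leaves experiment results unchanged", {
  q <- named_params("q_MC")
  grid <- small_match_grid()
  trial <- matching_trial(small_patterns()[["6"]], 0, id = "6")
  no_cache <- match_color(trial, q, grid, cheap_search())
  cache <- new.env(parent = emptyenv())
  with_cache1 <- match_color(trial, q, grid, cheap_search(), cache = cache)
  with_cache2 <- match_color(trial, q, grid, cheap_search(), cache = cache)
  expect_equal(no_cache$c_pred, with_cache1$c_pred)
  expect_equal(with_cache1$c_pred, with_cache2$c_pred)
  expect_gt(length(ls(cache)), 0)
})

test_that("the chromatic-disk emulation shifts colors away from the yellow surround", {
  q <- named_params("q_HSL")
  grid <- default_grid("hsl2d")
  yl <- hsl_to_disk(60, 0.5)
  yln <- yl / sqrt(sum(yl^2))
  sc <- search_config(refine = 3, refine_points = 5, temperature = 0.002)
  projs <- vapply(c(0, 120, 240), function(hue) {
    ct <- hsl_to_disk(hue, 0.5)
    pat <- square_surround(ct, yl, 0.5, 0.8)
    res <- match_color(matching_trial(pat, ct, id = hue), q, grid, sc)
    sum(res$shift * yln)
  }, 0)
  # each test color is pushed away from yellow (toward its blue opponent)
  expect_true(all(projs <= 0))
  expect_lt(mean(projs), -0.005)
})
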