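test_that("striped images lay out center, alternating surround, background", {
  grid <- small_match_grid()
  p <- lsY_to_opponent(s = 2.0)
  l <- lsY_to_opponent(s = 0.16)
  spec <- striped_pattern(0, p, l, stripe_width = 2, n_pairs = 2,
                          background_color = 0.5)
  img <- make_striped_image(spec, grid)
  sect <- img$values[, 1, 1]
  # center stripe at the middle 2 columns
  mid <- c(12, 13)
  expect_true(all(sect[mid] == 0))
  # outward: adjacent (p), second (l), adjacent, second, then background
  expect_true(all(sect[c(10, 11, 14, 15)] == p))
  expect_true(all(sect[c(8, 9, 16, 17)] == l))
  expect_true(all(sect[c(6, 7, 18, 19)] == p))
  expect_true(all(sect[c(4, 5, 20, 21)] == l))
  expect_true(all(sect[c(1:3, 22:24)] == 0.5))
  # mirror symmetry about the center axis
  expect_equal(sect, rev(sect))
  # constant along the second spatial axis
  expect_equal(img$values[, 2, 1], sect)
})

test_that("degenerate and swapped stripe specs behave as constructed", {
  grid <- small_match_grid()
  uni <- striped_pattern(0.3, 0.3, 0.3, stripe_width = 2, n_pairs = 2,
                         background_color = 0.3)
  expect_true(all(make_striped_image(uni, grid)$values == 0.3))
  pl <- striped_pattern(0, 1, -0.84, stripe_width = 2, n_pairs = 2)
  lp <- striped_pattern(0, -0.84, 1, stripe_width = 2, n_pairs = 2)
  a <- make_striped_image(pl, grid)$values
  b <- make_striped_image(lp, grid)$values
  # swapping the two surround colors maps one image onto the other
  swap <- a
  swap[a == 1] <- -0.84
  swap[a == -0.84] <- 1
  expect_equal(swap, b)
  # center stripe unchanged
  expect_equal(a[c(12, 13), , ], b[c(12, 13), , ])
  # geometry overflow is an error
  big <- striped_pattern(0, 1, -0.84, stripe_width = 4, n_pairs = 4)
  expect_error(make_striped_image(big, grid), "exceeds the spatial domain")
})

test_that("the eight canonical test patterns match the printed order", {
  pats <- enumerate_ms_patterns()
  expect_length(pats, 8)
  expect_equal(names(pats), as.character(0:7))
  p <- 1.0; l <- -0.84; w <- -0.02
  adj <- vapply(pats, function(x) x$adjacent_color, 0)
  sec <- vapply(pats, function(x) x$second_color, 0)
  expect_equal(unname(adj), c(p, l, p, l, w, w, p, l))
  expect_equal(unname(sec), c(p, l, w, w, p, l, l, p))
  expect_equal(pats[["0"]]$adjacent_color, pats[["0"]]$second_color)
  expect_equal(pats[["6"]]$adjacent_color, p)
  expect_equal(pats[["6"]]$second_color, l)
})

test_that("comparison images keep the central geometry on a neutral surround", {
  grid <- small_match_grid()
  tmpl <- striped_pattern(0, 1, -0.84, stripe_width = 2, n_pairs = 2)
  img <- make_comparison_image(0, tmpl, grid)
  expect_true(all(img$values == 0))
  img2 <- make_comparison_image(0.7, tmpl, grid)
  sect <- img2$values[, 1, 1]
  expect_equal(sect[c(12, 13)], c(0.7, 0.7))
  expect_true(all(sect[-c(12, 13)] == 0))
  # family evaluated at c_test differs from the test image only off-center
  test_img <- make_striped_image(tmpl, grid)
  at_ctest <- make_comparison_image(tmpl$center_color, tmpl, grid)
  diffs <- which(at_ctest$values != test_img$values, arr.ind = TRUE)
  expect_false(any(diffs[, 1] %in% c(12, 13)))
  expect_gt(nrow(diffs), 0)
  # 2D: the Gray comparison surround is the disk origin
  g2 <- domain_grid(9, 9, 0.2, color_dim = 2, nc = 5)
  sq <- square_surround(c(0.5, 0), hsl_to_disk(60, 0.5),
                        patch_half_width = 0.3, surround_half_width = 0.8)
  cmp <- make_comparison_image(hsl_to_disk(0, 0, 0.5), sq, g2)
  expect_true(all(cmp$values == 0))
})

test_that("square-in-surround images nest patch, surround, background", {
  g2 <- domain_grid(9, 9, 0.2, color_dim = 2, nc = 5)
  yl <- hsl_to_disk(60, 0.5)
  sq <- square_surround(c(0.5, 0), yl, patch_half_width = 0.2,
                        surround_half_width = 0.6,
                        background_color = c(0, 0))
  img <- make_square_image(sq, g2)
  ctr <- 5
  expect_equal(img$values[ctr, ctr, ], c(0.5, 0))
  expect_equal(img$values[ctr + 2, ctr, ], yl)   # 0.4 units: surround
  expect_equal(img$values[1, 1, ], c(0, 0))      # corner: background
  expect_error(square_surround(c(0.5, 0), yl, 0.7, 0.6),
               "surround_half_width > patch_half_width")
})

test_that("negating every stimulus color negates the image exactly", {
  grid <- small_match_grid()
  spec <- striped_pattern(0.4, 1, -0.84, stripe_width = 2, n_pairs = 2,
                          background_color = -0.3)
  neg <- striped_pattern(-0.4, -1, 0.84, stripe_width = 2, n_pairs = 2,
                         background_color = 0.3)
  expect_equal(make_striped_image(neg, grid)$values,
               -make_striped_image(spec, grid)$values)
  expect_equal(negate_image(make_striped_image(spec, grid))$values,
               -make_striped_image(spec, grid)$values)
})

test_that("the HSL test grid factorizes hues by saturations", {
  tests <- make_hsl_test_grid()
  expect_length(tests, 36)
  expect_true(all(vapply(tests, function(x) sqrt(sum(x^2)), 0) < 1))
  four <- make_hsl_test_grid(n_hues = 4, n_sats = 1, s_max = 1)
  expect_equal(four[[1]], c(1, 0))
  expect_equal(four[[2]], c(0, 1), tolerance = 1e-12)
  expect_equal(four[[3]], c(-1, 0), tolerance = 1e-12)
  expect_equal(four[[4]], c(0, -1), tolerance = 1e-12)
  sats <- vapply(make_hsl_test_grid(6, 3, s_max = 0.9),
                 function(x) sqrt(sum(x^2)), 0)
  expect_equal(sort(unique(round(sats, 10))), c(0.3, 0.6, 0.9))
})

test_that("images reject out-of-domain colors", {
  grid <- small_match_grid()
  vals <- array(0, dim = c(grid$nx, grid$ny, 1))
  vals[1, 1, 1] <- 2.5
  expect_error(cortical_image(vals, grid), "outside")
  g2 <- domain_grid(5, 5, 0.2, color_dim = 2, nc = 5)
  v2 <- array(0, dim = c(5, 5, 2))
  v2[3, 3, ] <- c(0.9, 0.9)
  expect_error(cortical_image(v2, g2), "outside the unit disk")
})
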