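# Shared fixtures: small grids and parameter draws used across test files.

tiny_grid_1d <- function(nx = 6, ny = 6, nc = 5, boundary = "zero") {
  domain_grid(nx, ny, 0.3, color_dim = 1, nc = nc, boundary = boundary)
}

tiny_grid_2d <- function(nx = 5, ny = 4, nc = 5, boundary = "zero") {
  domain_grid(nx, ny, 0.3, color_dim = 2, nc = nc, boundary = boundary)
}

# A small but non-degenerate grid for matching tests: striped patterns with
# 2-node stripes and 2 pairs per side fit in 24 columns.
small_match_grid <- function() domain_grid(24, 4, 0.1, color_dim = 1, nc = 21)

small_patterns <- function(c_test = 0) {
  enumerate_ms_patterns(c_test, stripe_width = 2, n_pairs = 2)
}

cheap_search <- function(...) {
  search_config(n_candidates = 21, refine = FALSE, ...)
}

# Random valid parameter vector (respects mu > nu and positivity).
random_params <- function() {
  model_params(
    mu_c = runif(1, 0.1, 1), nu_c = runif(1, 0.1, 1),
    alpha_c = runif(1, 0.2, 1.5), beta_c = runif(1, 0.2, 1.5),
    mu = runif(1, 2, 5), nu = runif(1, 0.5, 1.9),
    alpha = runif(1, 0.3, 1), beta = runif(1, 1, 10),
    mu_h = runif(1, 0.2, 1), sigma_h = runif(1, 0.2, 0.5),
    gamma = runif(1, 0.5, 3))
}

random_activity <- function(grid) {
  array(runif(prod(field_dim_for(grid)), 0.05, 0.95),
        dim = field_dim_for(grid))
}

# field_dim is internal; recompute the shape from exported pieces.
field_dim_for <- function(grid) {
  if (grid$d == 1) c(grid$nx, grid$ny, grid$nc)
  else c(grid$nx, grid$ny, grid$nc, grid$nc)
}

sym_flip_for <- function(values, grid) {
  if (grid$d == 1) values[, , rev(seq_len(grid$nc)), drop = FALSE]
  else values[, , rev(seq_len(grid$nc)), rev(seq_len(grid$nc)), drop = FALSE]
}
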