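#' Joint discretization of cortical space and opponent color space
#'
#' A `domain_grid` discretizes the product of a rectangular cortical patch
#' `Omega` (uniform spacing, centered on the origin) and the opponent color
#' space: either the interval `[-2, 2]` (1D setting) or a Cartesian grid on
#' `[-1, 1]^2` masked to the closed unit disk (2D setting). The color nodes
#' are symmetric under negation as a set, so the opponency reflection
#' `Sym: a(r, c) -> a(r, -c)` is an exact node permutation. Masked nodes of
#' the 2D color grid are pinned (excluded from integrals and norms).
#'
#' @param nx,ny number of spatial nodes along each axis.
#' @param spacing spatial node spacing (cortical length units).
#' @param color_dim dimension of the color space, 1 or 2.
#' @param nc number of color nodes per color axis (odd, so that the neutral
#'   color 0 is a node and the node set is negation-symmetric).
#' @param color_extent half-width of the color axis: 2 for the 1D interval,
#'   1 for the disk's bounding square.
#' @param boundary `"zero"` for zero-padded spatial convolution (default) or
#'   `"periodic"`.
#' @return an object of class `domain_grid`.
#' @export
domain_grid <- function(nx, ny, spacing, color_dim = 1,
                        nc = if (color_dim == 1) 41 else 11,
                        color_extent = if (color_dim == 1) 2 else 1,
                        boundary = c("zero", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(nx >= 1, ny >= 1, spacing > 0, color_dim %in% c(1, 2),
            nc >= 3, color_extent > 0)
  if (nc %% 2 == 0) {
    stop("nc must be odd so the color nodes are symmetric under negation")
  }
  cnodes <- seq(-color_extent, color_extent, length.out = nc)
  cnodes <- cnodes - cnodes[(nc + 1) / 2]  # exact 0 at the center node
  hc <- cnodes[2] - cnodes[1]
  g <- list(
    nx = nx, ny = ny, h = spacing,
    x = (seq_len(nx) - (nx + 1) / 2) * spacing,
    y = (seq_len(ny) - (ny + 1) / 2) * spacing,
    d = color_dim, nc = nc, hc = hc, cnodes = cnodes,
    boundary = boundary
  )
  if (color_dim == 1) {
    g$color_coords <- matrix(cnodes, ncol = 1)
    g$mask <- rep(TRUE, nc)
  } else {
    cc <- as.matrix(expand.grid(c1 = cnodes, c2 = cnodes))
    g$color_coords <- unname(cc)
    g$mask <- sqrt(rowSums(cc^2)) <= 1 + 1e-9
  }
  structure(g, class = "domain_grid")
}

#' @export
print.domain_grid <- function(x, ...) {
  cat(sprintf(
    "domain_grid: %d x %d spatial nodes (spacing %g), color dim %d (%d nodes/axis, spacing %g), %s boundary\n",
    x$nx, x$ny, x$h, x$d, x$nc, x$hc, x$boundary))
  if (x$d == 2) {
    cat(sprintf("  %d of %d color nodes inside the unit disk\n",
                sum(x$mask), length(x$mask)))
  }
  invisible(x)
}

#' Default grids for the two experimental settings
#'
#' Three presets are provided. `"ms1d"` is the striped-pattern setting: an
#' 80 x 8 cortical patch at spacing 0.05 with 41 color nodes on `[-2, 2]`;
#' the spacing is calibrated so that a stripe of 4 nodes is 0.2 length units
#' wide, which puts the excitatory center of the regressed spatial DOG
#' (sign-change radius about 0.77) across roughly 7 stripes.
#' `"ms1d_coarse"` is a reduced version (32 x 4 at spacing 0.1, 21 color
#' nodes) used for regression studies. `"hsl2d"` is the square-in-surround
#' setting on the chromatic disk: 17 x 17 spatial nodes at spacing 0.1 and
#' an 11 x 11 Cartesian color grid masked to the unit disk.
#'
#' @param setting one of `"ms1d"`, `"ms1d_coarse"`, `"hsl2d"`.
#' @param boundary spatial boundary handling, `"zero"` or `"periodic"`.
#' @return a `domain_grid`.
#' @export
default_grid <- function(setting = c("ms1d", "ms1d_coarse", "hsl2d"),
                         boundary = "zero") {
  setting <- match.arg(setting)
  switch(setting,
    ms1d = domain_grid(80, 8, 0.05, color_dim = 1, nc = 41,
                       boundary = boundary),
    ms1d_coarse = domain_grid(32, 4, 0.1, color_dim = 1, nc = 21,
                              boundary = boundary),
    hsl2d = domain_grid(17, 17, 0.1, color_dim = 2, nc = 11,
                        boundary = boundary)
  )
}

# Index (ix, iy) of the spatial node nearest the cortical origin.
grid_center <- function(grid) {
  c(which.min(abs(grid$x)), which.min(abs(grid$y)))
}

# Dimensions of a field array over the grid: (nx, ny, nc[, nc]).
field_dim <- function(grid) {
  if (grid$d == 1) as.integer(c(grid$nx, grid$ny, grid$nc))
  else as.integer(c(grid$nx, grid$ny, grid$nc, grid$nc))
}

# Logical mask over flattened color nodes (all TRUE in 1D).
color_mask <- function(grid) grid$mask

# Number of color nodes (flattened, including masked).
n_color_nodes <- function(grid) nrow(grid$color_coords)

# Reflect a field through color negation: (Sym a)(r, c) = a(r, -c).
# The color node set is negation-symmetric by construction, so this is an
# exact reversal of each color axis.
sym_flip <- function(values, grid) {
  if (grid$d == 1) {
    values[, , rev(seq_len(grid$nc)), drop = FALSE]
  } else {
    values[, , rev(seq_len(grid$nc)), rev(seq_len(grid$nc)), drop = FALSE]
  }
}

# Expand a per-color-node vector to a full field array (same value at every
# spatial node).
expand_color_profile <- function(v, grid) {
  array(rep(v, each = grid$nx * grid$ny), dim = field_dim(grid))
}

# Flatten the color axes of a field to one index: (nx*ny) x n_color matrix.
flatten_field <- function(values, grid) {
  matrix(values, nrow = grid$nx * grid$ny, ncol = n_color_nodes(grid))
}

unflatten_field <- function(m, grid) {
  array(m, dim = field_dim(grid))
}
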