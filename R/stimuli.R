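#' Striped test-pattern specification
#'
#' Concentric-ring stimuli are modeled as mirror-symmetric vertical stripes
#' (the same axial-symmetry reduction used to keep the numerics tractable): a
#' central test stripe, `n_pairs` pairs of (adjacent, second) stripes on each
#' side alternating outward, and a uniform background beyond. In the 1D
#' opponent setting the canonical colors are purple (`c = 1.0`, from
#' `s = 2.0`), lime (`c = -0.84`, `s = 0.16`) and white (`c = -0.02`,
#' `s = 0.98`).
#'
#' @param center_color opponent color of the central (test) stripe.
#' @param adjacent_color color of the stripes adjacent to the test stripe.
#' @param second_color color of the alternating second stripes.
#' @param stripe_width stripe width in spatial grid nodes.
#' @param n_pairs number of (adjacent, second) stripe pairs on each side.
#' @param background_color color outside the striped region.
#' @return an object of class `striped_pattern`.
#' @export
striped_pattern <- function(center_color, adjacent_color, second_color,
                            stripe_width = 4, n_pairs = 4,
                            background_color = 0) {
  stopifnot(stripe_width >= 1, stripe_width == round(stripe_width),
            n_pairs >= 1, n_pairs == round(n_pairs))
  d <- length(center_color)
  for (col in list(center_color, adjacent_color, second_color,
                   background_color)) {
    opponent_color(col, d = d)
  }
  structure(list(center_color = as.numeric(center_color),
                 adjacent_color = as.numeric(adjacent_color),
                 second_color = as.numeric(second_color),
                 stripe_width = as.integer(stripe_width),
                 n_pairs = as.integer(n_pairs),
                 background_color = as.numeric(background_color),
                 d = d),
            class = "striped_pattern")
}

#' Square-in-surround stimulus specification
#'
#' A central square patch inside a larger uniform square surround, the
#' geometry of the chromatic-disk matching experiments (colored square on a
#' Yellow test surround, matched against a Gray comparison surround).
#'
#' @param patch_color opponent color of the central patch.
#' @param surround_color opponent color of the surround square.
#' @param patch_half_width,surround_half_width half-widths in cortical length
#'   units; the patch must be strictly inside the surround.
#' @param background_color color beyond the surround square (defaults to the
#'   neutral origin).
#' @return an object of class `square_surround`.
#' @export
square_surround <- function(patch_color, surround_color,
                            patch_half_width = 0.3, surround_half_width = 1.0,
                            background_color = NULL) {
  d <- length(patch_color)
  if (is.null(background_color)) background_color <- rep(0, d)
  stopifnot(patch_half_width > 0, surround_half_width > patch_half_width)
  for (col in list(patch_color, surround_color, background_color)) {
    opponent_color(col, d = d)
  }
  structure(list(patch_color = as.numeric(patch_color),
                 surround_color = as.numeric(surround_color),
                 patch_half_width = patch_half_width,
                 surround_half_width = surround_half_width,
                 background_color = as.numeric(background_color),
                 d = d),
            class = "square_surround")
}

# Column membership of the striped layout: a list with the column indices of
# the central stripe and, per side offset k = 1..2*n_pairs, the stripe columns.
striped_columns <- function(spec, grid) {
  w <- spec$stripe_width
  n_stripes <- 1 + 4 * spec$n_pairs  # center + 2*n_pairs per side
  total <- n_stripes * w
  if (total > grid$nx) {
    stop("striped region (", total, " columns) exceeds the spatial domain (",
         grid$nx, " columns)")
  }
  lo <- floor((grid$nx - total) / 2)  # background columns on the left
  start <- lo + 1
  cols <- vector("list", n_stripes)
  for (i in seq_len(n_stripes)) {
    cols[[i]] <- seq(start + (i - 1) * w, length.out = w)
  }
  center_idx <- (n_stripes + 1) / 2
  list(cols = cols, center_idx = center_idx, n_stripes = n_stripes)
}

#' Render a striped pattern as a cortical image
#'
#' @param spec a [striped_pattern()].
#' @param grid a [domain_grid()] whose color dimension matches the spec.
#' @return a `cortical_image`: an array of dimension `(nx, ny, d)` with the
#'   grid attached.
#' @export
make_striped_image <- function(spec, grid) {
  stopifnot(inherits(spec, "striped_pattern"), inherits(grid, "domain_grid"))
  if (spec$d != grid$d) stop("pattern color dimension does not match the grid")
  lay <- striped_columns(spec, grid)
  img <- array(rep(spec$background_color, each = grid$nx * grid$ny),
               dim = c(grid$nx, grid$ny, grid$d))
  for (i in seq_len(lay$n_stripes)) {
    off <- abs(i - lay$center_idx)
    col <- if (off == 0) {
      spec$center_color
    } else if (off %% 2 == 1) {
      spec$adjacent_color
    } else {
      spec$second_color
    }
    img[lay$cols[[i]], , ] <- rep(col, each = length(lay$cols[[i]]) * grid$ny)
  }
  cortical_image(img, grid)
}

#' Render a square-in-surround stimulus as a cortical image
#'
#' @param spec a [square_surround()].
#' @param grid a [domain_grid()] with 2D color (or 1D, for achromatic axes).
#' @return a `cortical_image`.
#' @export
make_square_image <- function(spec, grid) {
  stopifnot(inherits(spec, "square_surround"), inherits(grid, "domain_grid"))
  if (spec$d != grid$d) stop("pattern color dimension does not match the grid")
  if (spec$patch_half_width > max(abs(grid$x)) ||
      spec$patch_half_width > max(abs(grid$y))) {
    stop("patch exceeds the spatial domain")
  }
  img <- array(rep(spec$background_color, each = grid$nx * grid$ny),
               dim = c(grid$nx, grid$ny, grid$d))
  ax <- abs(grid$x); ay <- abs(grid$y)
  in_sur <- outer(ax <= spec$surround_half_width + 1e-12,
                  ay <= spec$surround_half_width + 1e-12, `&`)
  in_patch <- outer(ax <= spec$patch_half_width + 1e-12,
                    ay <= spec$patch_half_width + 1e-12, `&`)
  for (k in seq_len(spec$d)) {
    plane <- img[, , k]
    plane[in_sur] <- spec$surround_color[k]
    plane[in_patch] <- spec$patch_color[k]
    img[, , k] <- plane
  }
  cortical_image(img, grid)
}

#' Cortical image container
#'
#' A field over the spatial grid with one opponent color per node, i.e. an
#' array of dimension `(nx, ny, d)`. Retinotopy is taken as the identity:
#' stimuli are specified directly in cortical coordinates.
#'
#' @param values numeric array `(nx, ny, d)`.
#' @param grid the `domain_grid` the image lives on.
#' @return an object of class `cortical_image`.
#' @export
cortical_image <- function(values, grid) {
  stopifnot(inherits(grid, "domain_grid"))
  values <- as.array(values)
  if (length(dim(values)) == 2 && grid$d == 1) {
    dim(values) <- c(dim(values), 1)
  }
  if (length(dim(values)) != 3 ||
      !all(dim(values) == c(grid$nx, grid$ny, grid$d))) {
    stop("image dimensions ", paste(dim(values), collapse = "x"),
         " do not match the grid (", grid$nx, "x", grid$ny, "x", grid$d, ")")
  }
  if (grid$d == 1) {
    if (any(abs(values) > 2 + 1e-9)) {
      stop("image contains colors outside [-2, 2]")
    }
  } else {
    nr <- sqrt(values[, , 1]^2 + values[, , 2]^2)
    if (any(nr > 1 + 1e-9)) stop("image contains colors outside the unit disk")
  }
  structure(list(values = values, grid = grid), class = "cortical_image")
}

#' @export
print.cortical_image <- function(x, ...) {
  cat(sprintf("cortical_image on %dx%d grid, color dim %d, range [%.3g, %.3g]\n",
              x$grid$nx, x$grid$ny, x$grid$d,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Negate every color of a cortical image
#'
#' @param img a `cortical_image`.
#' @return the image `-I`, each color replaced by its opponent.
#' @export
negate_image <- function(img) {
  cortical_image(-img$values, img$grid)
}

# Canonical 1D chromaticities: purple, lime, white as c = s - 1.
ms_colors <- function() {
  c(p = lsY_to_opponent(s = 2.0),
    l = lsY_to_opponent(s = 0.16),
    w = lsY_to_opponent(s = 0.98))
}

#' The eight striped test patterns of the ring-matching experiments
#'
#' Returns the ordered list of patterns indexed `i = 0, ..., 7`:
#' p/p, l/l, p/w, l/w, w/p, w/l, p/l, l/p, where the notation a/b means
#' adjacent-stripe color a and second-stripe color b, with p = purple
#' (`c = 1.0`), l = lime (`c = -0.84`), w = white (`c = -0.02`).
#'
#' @param c_test opponent color of the central test stripe (default the
#'   neutral 0).
#' @param stripe_width,n_pairs stripe geometry, see [striped_pattern()].
#' @param background_color background color (default neutral).
#' @return a named list of 8 `striped_pattern` objects, names `"0"` to `"7"`.
#' @export
enumerate_ms_patterns <- function(c_test = 0, stripe_width = 4, n_pairs = 4,
                                  background_color = 0) {
  ab <- list(c("p", "p"), c("l", "l"), c("p", "w"), c("l", "w"),
             c("w", "p"), c("w", "l"), c("p", "l"), c("l", "p"))
  cols <- ms_colors()
  out <- lapply(ab, function(x) {
    striped_pattern(center_color = c_test,
                    adjacent_color = cols[[x[1]]],
                    second_color = cols[[x[2]]],
                    stripe_width = stripe_width, n_pairs = n_pairs,
                    background_color = background_color)
  })
  names(out) <- as.character(0:7)
  out
}

#' Comparison image for a matching trial
#'
#' The comparison image keeps the central geometry of the test pattern (the
#' test stripe or patch) filled with the candidate color `c`, with everything
#' else set to the neutral comparison surround: the origin in the 1D setting,
#' or a configurable surround (Gray, the disk origin, by default) in the 2D
#' setting.
#'
#' @param c candidate comparison color.
#' @param template a `striped_pattern` or `square_surround` giving the central
#'   geometry.
#' @param grid the `domain_grid`.
#' @param surround_color comparison surround color (default the neutral
#'   origin).
#' @return a `cortical_image`.
#' @export
make_comparison_image <- function(c, template, grid, surround_color = NULL) {
  d <- grid$d
  c <- opponent_color(c, d = d)
  if (is.null(surround_color)) surround_color <- rep(0, d)
  surround_color <- opponent_color(surround_color, d = d)
  if (inherits(template, "striped_pattern")) {
    spec <- striped_pattern(center_color = c,
                            adjacent_color = surround_color,
                            second_color = surround_color,
                            stripe_width = template$stripe_width,
                            n_pairs = template$n_pairs,
                            background_color = surround_color)
    make_striped_image(spec, grid)
  } else if (inherits(template, "square_surround")) {
    spec <- square_surround(patch_color = c,
                            surround_color = surround_color,
                            patch_half_width = template$patch_half_width,
                            surround_half_width = template$surround_half_width,
                            background_color = surround_color)
    make_square_image(spec, grid)
  } else {
    stop("template must be a striped_pattern or square_surround")
  }
}

#' Regularly spaced test colors on the chromatic disk
#'
#' Builds the `n_hues x n_sats` grid of test colors used by the
#' chromatic-disk matching emulation: hues equally spaced over `[0, 360)`
#' degrees and saturations equally spaced in `(0, s_max]`. The default
#' 12 x 3 factorization yields the 36 test points.
#'
#' @param n_hues,n_sats numbers of hue and saturation steps.
#' @param s_max largest saturation (kept below 1 so matched colors can move
#'   outward within the disk).
#' @return a list of 2D opponent colors, length `n_hues * n_sats`.
#' @export
make_hsl_test_grid <- function(n_hues = 12, n_sats = 3, s_max = 0.75) {
  stopifnot(n_hues >= 1, n_sats >= 1, s_max > 0, s_max <= 1)
  hues <- seq(0, 360, length.out = n_hues + 1)[seq_len(n_hues)]
  sats <- seq_len(n_sats) / n_sats * s_max
  out <- list()
  for (s in sats) {
    for (h in hues) {
      out[[length(out) + 1]] <- hsl_to_disk(h, s)
    }
  }
  out
}
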