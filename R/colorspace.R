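#' Opponent color coordinates
#'
#' The model works in a symmetric opponent representation of color space:
#' negating a coordinate vector maps a color to its Hering opponent, and the
#' origin is the self-opponent neutral gray. Two concrete representations are
#' supported: a one-dimensional interval `[-2, 2]` built from the
#' S-cone chromaticity (`c = s - 1`), and the two-dimensional unit chromatic
#' disk carved out of the HSL cylinder at constant luminance.
#'
#' @param coords numeric vector of length 1 or 2 (opponent coordinates).
#' @param d color-space dimension the coordinates must live in (1 or 2);
#'   defaults to `length(coords)`.
#' @return `coords` as a plain numeric vector, validated.
#' @examples
#' opponent_color(1)          # purple in the 1D setting (s = 2)
#' opponent_color(c(0.25, 0.43))
#' @export
opponent_color <- function(coords, d = length(coords)) {
  coords <- as.numeric(coords)
  if (length(coords) != d) {
    stop("opponent color has dimension ", length(coords), ", expected ", d)
  }
  if (any(!is.finite(coords))) stop("opponent coordinates must be finite")
  if (d == 1) {
    if (abs(coords) > 2 + 1e-12) {
      stop("1D opponent coordinate ", coords, " outside the interval [-2, 2]")
    }
  } else if (d == 2) {
    if (sqrt(sum(coords^2)) > 1 + 1e-9) {
      stop("2D opponent coordinates outside the unit chromatic disk")
    }
  } else {
    stop("opponent color dimension must be 1 or 2")
  }
  coords
}

#' Convert an (l, s, Y) chromaticity triple to a 1D opponent coordinate
#'
#' The cone-ratio representation uses `s = S/(L+M)`, `l = L/(L+M)` and
#' luminance `Y`. The one-dimensional opponent coordinate is the shifted
#' S-chromaticity `c = s - 1`, confined to `[-2, 2]`; `l` and `Y` are carried
#' by independent axes and ignored here.
#'
#' @param l,s,Y the chromaticity coordinates; only `s` enters the result.
#' @return a 1D opponent coordinate.
#' @examples
#' lsY_to_opponent(s = 2.0)   # purple ->  1.0
#' lsY_to_opponent(s = 0.16)  # lime   -> -0.84
#' @export
lsY_to_opponent <- function(l = NULL, s, Y = NULL) {
  if (!is.numeric(s) || length(s) != 1 || !is.finite(s)) {
    stop("s chromaticity must be a finite scalar")
  }
  if (s < 0 || s > 4) {
    stop("s chromaticity ", s, " outside the admissible interval [0, 4]")
  }
  opponent_color(s - 1, d = 1)
}

#' Map an HSL triple onto the unit chromatic disk
#'
#' The constant-luminance cut of the HSL cylinder is identified with the unit
#' disk via `(c1, c2) = (S cos H, S sin H)`. Hue is measured in degrees,
#' counterclockwise from the positive `c1` axis. Luminance is dropped
#' (the disk lives at a fixed luminance plane).
#'
#' @param H hue in degrees, `[0, 360)`.
#' @param S saturation fraction in `[0, 1]`.
#' @param L luminance fraction in `[0, 1]` (ignored).
#' @return a 2D opponent coordinate on the unit disk.
#' @examples
#' hsl_to_disk(60, 0.5)  # the Yellow surround of the square experiments
#' @export
hsl_to_disk <- function(H, S, L = 0.5) {
  stopifnot(is.finite(H), is.finite(S), S >= 0, S <= 1)
  th <- H * pi / 180
  opponent_color(c(S * cos(th), S * sin(th)), d = 2)
}

#' Invert the disk embedding back to HSL
#'
#' @param c2d a 2D opponent coordinate (inside the unit disk).
#' @param L luminance fraction to attach (pass-through constant).
#' @return list with components `H` (degrees in `[0, 360)`), `S`, `L`.
#'   At the origin the hue is undefined and reported as 0 by convention.
#' @export
disk_to_hsl <- function(c2d, L = 0.5) {
  c2d <- opponent_color(c2d, d = 2)
  S <- sqrt(sum(c2d^2))
  H <- if (S == 0) 0 else (atan2(c2d[2], c2d[1]) * 180 / pi) %% 360
  list(H = H, S = S, L = L)
}

#' Convert sRGB fractions to HSL
#'
#' Standard computer-graphics max/min chroma formula mapping the sRGB unit
#' cube to the HSL cylinder.
#'
#' @param r,g,b color components in `[0, 1]`.
#' @return list with `H` (degrees in `[0, 360)`), `S`, `L` (fractions).
#' @examples
#' srgb_to_hsl(1, 1, 0)  # yellow: H = 60, S = 1, L = 0.5
#' @export
srgb_to_hsl <- function(r, g, b) {
  stopifnot(r >= 0, r <= 1, g >= 0, g <= 1, b >= 0, b <= 1)
  mx <- max(r, g, b)
  mn <- min(r, g, b)
  L <- (mx + mn) / 2
  if (mx == mn) {
    return(list(H = 0, S = 0, L = L))
  }
  d <- mx - mn
  S <- if (L > 0.5) d / (2 - mx - mn) else d / (mx + mn)
  H <- if (mx == r) {
    ((g - b) / d) %% 6
  } else if (mx == g) {
    (b - r) / d + 2
  } else {
    (r - g) / d + 4
  }
  list(H = (H * 60) %% 360, S = S, L = L)
}

#' Parse a color written in one of the config notations
#'
#' Recognizes `"lsY:<l>,<s>,<Y>"`, `"hsl:<H>,<S>,<L>"` (S and L as fractions)
#' and `"opp:<c1>[,<c2>]"`. `lsY` yields a 1D opponent coordinate, `hsl` a 2D
#' one, and `opp` whichever dimension is written.
#'
#' @param x a single string.
#' @return an opponent coordinate vector (length 1 or 2).
#' @examples
#' parse_color("lsY:0.66,2.0,15")
#' parse_color("hsl:60,0.5,0.5")
#' parse_color("opp:-0.84")
#' @export
parse_color <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  m <- regmatches(x, regexec("^([a-zA-Z]+):(.*)$", x))[[1]]
  if (length(m) != 3) stop("unparseable color spec: ", x)
  tag <- tolower(m[2])
  vals <- suppressWarnings(as.numeric(strsplit(m[3], ",")[[1]]))
  if (any(is.na(vals))) stop("non-numeric component in color spec: ", x)
  switch(tag,
    lsy = {
      if (length(vals) != 3) stop("lsY spec needs 3 components: ", x)
      lsY_to_opponent(vals[1], vals[2], vals[3])
    },
    hsl = {
      if (length(vals) != 3) stop("hsl spec needs 3 components: ", x)
      hsl_to_disk(vals[1], vals[2], vals[3])
    },
    opp = {
      if (!length(vals) %in% c(1, 2)) stop("opp spec needs 1 or 2 components: ", x)
      opponent_color(vals)
    },
    stop("unknown color notation '", tag, "' in: ", x)
  )
}

#' Format an opponent coordinate in the `opp:` notation
#'
#' @param coords opponent coordinate vector.
#' @return a string `"opp:..."` that [parse_color()] reads back.
#' @export
format_color <- function(coords) {
  paste0("opp:", paste(format(coords, digits = 17, scientific = FALSE,
                              trim = TRUE), collapse = ","))
}
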