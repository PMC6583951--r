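#' Search configuration for matching emulation
#'
#' Controls the discrete search over candidate comparison colors and the
#' steady-state solver used inside it. The candidate lattice has
#' `n_candidates` equally spaced points over `[-2, 2]` in the 1D setting, or
#' a polar lattice (disk center plus `n_hues x n_radii` points up to radius
#' `s_lattice_max`) in the 2D setting. The SoftMin temperature `temperature`
#' smooths the discrete minimizer; `temperature = 0` gives the hard argmin.
#' `refine` local refinement passes telescope around the best cell: each
#' pass lays `refine_points` points per axis across the previous spacing and
#' shrinks the spacing accordingly, so the search resolution improves
#' geometrically while the number of solves stays small.
#'
#' @param n_candidates number of 1D lattice points (default 41).
#' @param temperature SoftMin temperature in distance units (default 0.01).
#' @param refine number of local refinement passes (`TRUE` = 1, `FALSE` or
#'   0 = none; default 1).
#' @param refine_points points in the refinement lattice per axis.
#' @param n_hues,n_radii polar lattice resolution for 2D searches.
#' @param s_lattice_max outermost candidate radius in the disk.
#' @param tol,max_iter steady-state solver settings.
#' @return an object of class `search_config`.
#' @export
search_config <- function(n_candidates = 41, temperature = 0.01,
                          refine = TRUE, refine_points = 9,
                          n_hues = 12, n_radii = 4, s_lattice_max = 0.96,
                          tol = 1e-3, max_iter = 100) {
  refine <- as.integer(refine)  # TRUE -> 1, FALSE -> 0
  stopifnot(n_candidates >= 3, temperature >= 0, refine >= 0,
            refine_points >= 3,
            n_hues >= 3, n_radii >= 1, s_lattice_max > 0, s_lattice_max <= 1,
            tol > 0, max_iter >= 1)
  structure(list(n_candidates = n_candidates, temperature = temperature,
                 refine = refine, refine_points = refine_points,
                 n_hues = n_hues, n_radii = n_radii,
                 s_lattice_max = s_lattice_max,
                 tol = tol, max_iter = max_iter),
            class = "search_config")
}

# Coarse candidate lattice for a grid's color dimension: matrix (n x d).
candidate_lattice <- function(grid, search) {
  if (grid$d == 1) {
    matrix(seq(-2, 2, length.out = search$n_candidates), ncol = 1)
  } else {
    hues <- seq(0, 2 * pi, length.out = search$n_hues + 1)[seq_len(search$n_hues)]
    radii <- seq_len(search$n_radii) / search$n_radii * search$s_lattice_max
    pts <- cbind(0, 0)
    for (r in radii) pts <- rbind(pts, cbind(r * cos(hues), r * sin(hues)))
    pts
  }
}

# Spacing of the coarse lattice (used for refinement windows and the
# resolution quoted in recovery checks).
lattice_spacing <- function(grid, search) {
  if (grid$d == 1) 4 / (search$n_candidates - 1)
  else search$s_lattice_max / search$n_radii
}

# Refinement lattice around a best candidate, clipped to the color domain.
refinement_lattice <- function(best, grid, search, sp) {
  offs <- seq(-sp, sp, length.out = search$refine_points)
  if (grid$d == 1) {
    pts <- matrix(best[1] + offs, ncol = 1)
    pts[pts[, 1] >= -2 & pts[, 1] <= 2, , drop = FALSE]
  } else {
    pts <- as.matrix(expand.grid(best[1] + offs, best[2] + offs))
    pts[sqrt(rowSums(pts^2)) <= 1, , drop = FALSE]
  }
}

#' Sup-norm distance between two color sensations
#'
#' The perceptual similarity criterion used for matching: the L-infinity
#' distance over the color nodes, `sup_c |a1(c) - a2(c)|`.
#'
#' @param a1,a2 `color_sensation` objects on the same color grid.
#' @return a non-negative scalar, zero iff the tabulated profiles coincide.
#' @export
sensation_distance <- function(a1, a2) {
  stopifnot(inherits(a1, "color_sensation"), inherits(a2, "color_sensation"))
  if (length(a1$values) != length(a2$values) ||
      !isTRUE(all.equal(a1$coords, a2$coords, tolerance = 1e-12))) {
    stop("sensations live on different color grids")
  }
  max(abs(a1$values - a2$values))
}

# SoftMin-weighted minimizer over candidates (rows of `cands`) with
# distances `d`. Temperature 0 gives the hard argmin.
softmin_combine <- function(cands, d, temperature) {
  if (temperature <= 0) return(cands[which.min(d), ])
  w <- exp(-(d - min(d)) / temperature)
  as.numeric(colSums(cands * w) / sum(w))
}

#' Matching trial specification
#'
#' A test pattern (striped or square-in-surround) whose central color is
#' `c_test`, to be matched against the family of comparison images sharing
#' the central geometry on a neutral surround. `observed` optionally records
#' the color matched by an observer (or a synthetic one).
#'
#' @param pattern a `striped_pattern` or `square_surround`; its central color
#'   is overridden by `c_test`.
#' @param c_test the test color.
#' @param observed observed matched color, or `NULL`.
#' @param r_test,r_comp spatial node indices `c(ix, iy)` where sensations are
#'   read out; default the node nearest the cortical origin.
#' @param comp_surround comparison surround color; default the neutral origin.
#' @param id optional trial / pattern identifier carried into result tables.
#' @return an object of class `matching_trial`.
#' @export
matching_trial <- function(pattern, c_test, observed = NULL, r_test = NULL,
                           r_comp = NULL, comp_surround = NULL, id = NA) {
  stopifnot(inherits(pattern, "striped_pattern") ||
              inherits(pattern, "square_surround"))
  c_test <- opponent_color(c_test, d = pattern$d)
  if (!is.null(observed)) observed <- opponent_color(observed, d = pattern$d)
  structure(list(pattern = pattern, c_test = c_test, observed = observed,
                 r_test = r_test, r_comp = r_comp,
                 comp_surround = comp_surround, id = id),
            class = "matching_trial")
}

# Test image of a trial: the pattern with its central color set to c_test.
trial_test_image <- function(trial, grid) {
  p <- trial$pattern
  if (inherits(p, "striped_pattern")) {
    p$center_color <- trial$c_test
    make_striped_image(p, grid)
  } else {
    p$patch_color <- trial$c_test
    make_square_image(p, grid)
  }
}

# Geometry signature of the comparison family (for caching): comparison
# sensations depend only on the central geometry, the surround and c.
comparison_key <- function(trial, cc) {
  p <- trial$pattern
  geom <- if (inherits(p, "striped_pattern")) {
    paste("s", p$stripe_width, p$n_pairs)
  } else {
    paste("q", p$patch_half_width, p$surround_half_width)
  }
  sur <- if (is.null(trial$comp_surround)) "0" else
    paste(trial$comp_surround, collapse = ",")
  paste(geom, sur, paste(sprintf("%.12g", cc), collapse = ","), sep = "|")
}

comparison_sensation <- function(cc, trial, grid, q, search, op, cache) {
  key <- comparison_key(trial, cc)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  img <- make_comparison_image(cc, trial$pattern, grid,
                               surround_color = trial$comp_surround)
  ss <- suppressWarnings(
    steady_state(img, q, tol = search$tol, max_iter = search$max_iter,
                 op = op))
  sen <- suppressWarnings(color_sensation(ss, r0 = trial$r_comp))
  sen$converged_solver <- ss$converged
  if (!is.null(cache)) cache[[key]] <- sen
  sen
}

#' Emulate one asymmetric color-matching trial
#'
#' Computes the test sensation once, scans a coarse lattice of candidate
#' comparison colors, evaluates the sup-norm distance between test and
#' comparison sensations for each, and returns the SoftMin-weighted
#' minimizer (optionally after one local refinement pass around the best
#' coarse cell).
#'
#' @param trial a [matching_trial()].
#' @param q a `cnf_params` object.
#' @param grid a `domain_grid` matching the trial's color dimension.
#' @param search a [search_config()].
#' @param cache optional environment used to share comparison sensations
#'   across trials with the same comparison family.
#' @param op optional precomputed [field_operator()].
#' @return an object of class `match_result`: the predicted match `c_pred`,
#'   the `shift = c_pred - c_test`, the searched distance profile, and
#'   solver diagnostics.
#' @export
match_color <- function(trial, q, grid, search = search_config(),
                        cache = NULL, op = NULL) {
  stopifnot(inherits(trial, "matching_trial"), inherits(grid, "domain_grid"))
  if (trial$pattern$d != grid$d) {
    stop("trial color dimension does not match the grid")
  }
  if (is.null(op)) op <- field_operator(q, grid)
  ss_test <- suppressWarnings(
    steady_state(trial_test_image(trial, grid), q, tol = search$tol,
                 max_iter = search$max_iter, op = op))
  a_test <- suppressWarnings(color_sensation(ss_test, r0 = trial$r_test))
  cands <- candidate_lattice(grid, search)
  all_conv <- ss_test$converged
  eval_cands <- function(pts) {
    d <- numeric(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      sen <- comparison_sensation(pts[i, ], trial, grid, q, search, op, cache)
      if (!isTRUE(sen$converged_solver)) all_conv <<- FALSE
      d[i] <- sensation_distance(a_test, sen)
    }
    d
  }
  d <- eval_cands(cands)
  best <- cands[which.min(d), ]
  profile <- data.frame(cands, dist = d)
  names(profile)[seq_len(grid$d)] <- paste0("c", seq_len(grid$d))
  if (search$refine >= 1) {
    sp <- lattice_spacing(grid, search)
    rl <- NULL
    dr <- NULL
    rbest <- best
    for (pass in seq_len(search$refine)) {
      rl <- refinement_lattice(rbest, grid, search, sp)
      dr <- eval_cands(rl)
      rbest <- rl[which.min(dr), ]
      sp <- 2 * sp / (search$refine_points - 1)  # spacing of this pass
    }
    c_pred <- softmin_combine(rl, dr, search$temperature)
    rprofile <- data.frame(rl, dist = dr)
    names(rprofile)[seq_len(grid$d)] <- paste0("c", seq_len(grid$d))
  } else {
    c_pred <- softmin_combine(cands, d, search$temperature)
    rprofile <- NULL
  }
  structure(list(c_pred = c_pred, c_test = trial$c_test,
                 shift = c_pred - trial$c_test,
                 distance_profile = profile,
                 refined_profile = rprofile,
                 coarse_best = best,
                 diagnostics = list(test_iterations = ss_test$n_iter,
                                    all_converged = all_conv),
                 id = trial$id),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: c_test (%s) -> c_pred (%s), shift (%s)%s\n",
              paste(round(x$c_test, 4), collapse = ", "),
              paste(round(x$c_pred, 4), collapse = ", "),
              paste(round(x$shift, 4), collapse = ", "),
              if (x$diagnostics$all_converged) "" else " [non-converged]"))
  invisible(x)
}

#' Run a set of matching trials and tabulate the shifts
#'
#' Comparison sensations are cached across trials sharing a comparison
#' family, which leaves results unchanged (the solve is a pure function of
#' the candidate color and geometry). Per-trial solver failures are recorded
#' in the `converged` column and the run continues.
#'
#' @param trials list of [matching_trial()] objects on one grid/setting.
#' @param q a `cnf_params` object.
#' @param grid a `domain_grid`.
#' @param search a [search_config()].
#' @return a data frame with one row per trial: pattern id, test color,
#'   predicted match, shift (per color axis) and the convergence flag. The
#'   `match_result` objects are attached as attribute `"results"`.
#' @export
run_experiment <- function(trials, q, grid, search = search_config()) {
  stopifnot(length(trials) >= 1)
  op <- field_operator(q, grid)
  cache <- new.env(parent = emptyenv())
  res <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    res[[i]] <- match_color(trials[[i]], q, grid, search, cache = cache,
                            op = op)
  }
  d <- grid$d
  tab <- data.frame(
    id = vapply(trials, function(t) as.character(t$id), character(1)),
    stringsAsFactors = FALSE)
  for (k in seq_len(d)) {
    tab[[paste0("c_test_", k)]] <- vapply(res, function(r) r$c_test[k], 0)
    tab[[paste0("c_pred_", k)]] <- vapply(res, function(r) r$c_pred[k], 0)
    tab[[paste0("shift_", k)]] <- vapply(res, function(r) r$shift[k], 0)
  }
  tab$converged <- vapply(res, function(r) r$diagnostics$all_converged, NA)
  if (!all(tab$converged)) {
    warning(sum(!tab$converged), " trial(s) involved non-converged steady states")
  }
  attr(tab, "results") <- res
  tab
}

#' Shift predictions for the eight striped test patterns
#'
#' Builds the eight canonical patterns (p/p, l/l, p/w, l/w, w/p, w/l, p/l,
#' l/p) with a common test color and runs the matching emulation for each.
#'
#' @param q a `cnf_params` object.
#' @param c_test test color of the central stripe (default neutral 0).
#' @param grid a 1D-color `domain_grid` (default [default_grid()] `"ms1d"`).
#' @param search a [search_config()].
#' @param stripe_width,n_pairs stripe geometry passed to
#'   [enumerate_ms_patterns()].
#' @return the [run_experiment()] table, 8 rows indexed 0..7.
#' @export
ms_shift_experiment <- function(q, c_test = 0, grid = default_grid("ms1d"),
                                search = search_config(),
                                stripe_width = 4, n_pairs = 4) {
  pats <- enumerate_ms_patterns(c_test, stripe_width = stripe_width,
                                n_pairs = n_pairs)
  trials <- lapply(names(pats), function(nm) {
    matching_trial(pats[[nm]], c_test, id = nm)
  })
  run_experiment(trials, q, grid, search)
}

#' Shift predictions over the chromatic-disk test grid
#'
#' Emulates the square-in-surround experiment: each test color from the
#' regularly spaced HSL grid is shown in a square patch on the Yellow test
#' surround and matched against the comparison family on the Gray surround
#' (the disk origin). With the default 12 x 3 test grid this produces 36
#' (test, match) pairs.
#'
#' @param q a `cnf_params` object (typically `named_params("q_HSL")`).
#' @param grid a 2D-color `domain_grid` (default [default_grid()] `"hsl2d"`).
#' @param search a [search_config()]; the default uses three telescoping
#'   refinement passes (final spacing 0.03 in disk units) and a colder
#'   SoftMin (`T = 0.002`) than the 1D setting, because the
#'   sup-norm distance basins on the disk are shallow (depth of order 1e-3)
#'   and a larger temperature would average them away.
#' @param n_hues,n_sats,s_max test grid, see [make_hsl_test_grid()].
#' @param test_surround surround of the test image (default Yellow,
#'   HSL (60, 50%, 50%)).
#' @param patch_half_width,surround_half_width square geometry.
#' @return the [run_experiment()] table, one row per test color.
#' @export
hsl_shift_experiment <- function(q, grid = default_grid("hsl2d"),
                                 search = search_config(
                                   refine = 3, refine_points = 5,
                                   temperature = 0.002),
                                 n_hues = 12, n_sats = 3, s_max = 0.75,
                                 test_surround = hsl_to_disk(60, 0.5),
                                 patch_half_width = 0.5,
                                 surround_half_width = 0.8) {
  tests <- make_hsl_test_grid(n_hues, n_sats, s_max)
  trials <- lapply(seq_along(tests), function(i) {
    pat <- square_surround(patch_color = tests[[i]],
                           surround_color = test_surround,
                           patch_half_width = patch_half_width,
                           surround_half_width = surround_half_width)
    matching_trial(pat, tests[[i]], id = i)
  })
  run_experiment(trials, q, grid, search)
}
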