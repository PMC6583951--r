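#' Load and validate a run configuration
#'
#' Run configurations are YAML files with the sections below; unknown keys
#' anywhere are errors (no silent typos), and every omitted key is filled
#' with its default so the returned object is fully materialized.
#'
#' ```yaml
#' setting: ms1d          # or hsl2d
#' seed: 1
#' grid:                  # optional; defaults to the setting's preset
#'   nx: 80
#'   ny: 8
#'   spacing: 0.05
#'   nc: 41
#'   boundary: zero
#' stimulus:
#'   stripe_width: 4      # ms1d
#'   n_pairs: 4
#'   c_test: "opp:0"
#'   patch_half_width: 0.5       # hsl2d
#'   surround_half_width: 0.8
#'   test_surround: "hsl:60,0.5,0.5"
#' params: q_MC           # named fixture, or an 11-number list
#' search:
#'   n_candidates: 41
#'   temperature: 0.01
#'   refine: true
#'   tol: 1.0e-3
#'   max_iter: 100
#' ```
#'
#' @param path path to a YAML config file.
#' @return an object of class `run_config`: list with elements `setting`,
#'   `seed`, `grid` (a `domain_grid`), `stimulus` (list), `params`
#'   (`cnf_params`), `search` (`search_config`), plus `raw` (the merged
#'   key-value tree, round-trippable via [save_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  build_config(raw)
}

#' @rdname load_config
#' @param config a `run_config` object.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown config key(s) under '", where, "': ",
         paste(extra, collapse = ", "))
  }
}

default_or <- function(x, key, default) {
  if (is.null(x[[key]])) default else x[[key]]
}

build_config <- function(raw) {
  check_keys(raw, c("setting", "seed", "grid", "stimulus", "params",
                    "search"), "top level")
  setting <- default_or(raw, "setting", "ms1d")
  if (!setting %in% c("ms1d", "hsl2d")) {
    stop("config field 'setting' must be 'ms1d' or 'hsl2d'")
  }
  d <- if (setting == "ms1d") 1 else 2
  seed <- as.integer(default_or(raw, "seed", 1))

  gr <- default_or(raw, "grid", list())
  check_keys(gr, c("nx", "ny", "spacing", "nc", "boundary"), "grid")
  preset <- default_grid(setting)
  grid <- domain_grid(
    nx = default_or(gr, "nx", preset$nx),
    ny = default_or(gr, "ny", preset$ny),
    spacing = default_or(gr, "spacing", preset$h),
    color_dim = d,
    nc = default_or(gr, "nc", preset$nc),
    boundary = default_or(gr, "boundary", preset$boundary))

  st <- default_or(raw, "stimulus", list())
  check_keys(st, c("stripe_width", "n_pairs", "c_test", "patch_half_width",
                   "surround_half_width", "test_surround"), "stimulus")
  c_test_spec <- default_or(st, "c_test", if (d == 1) "opp:0" else "opp:0,0")
  c_test <- parse_color(c_test_spec)
  if (length(c_test) != d) {
    stop("stimulus.c_test has dimension ", length(c_test),
         " but setting '", setting, "' needs dimension ", d)
  }
  sur_spec <- default_or(st, "test_surround", "hsl:60,0.5,0.5")
  stimulus <- list(
    stripe_width = default_or(st, "stripe_width", 4),
    n_pairs = default_or(st, "n_pairs", 4),
    c_test = c_test,
    patch_half_width = default_or(st, "patch_half_width", 0.5),
    surround_half_width = default_or(st, "surround_half_width", 0.8),
    test_surround = if (d == 2) parse_color(sur_spec) else NULL)

  pr <- default_or(raw, "params", "q_MC")
  params <- if (is.character(pr) && length(pr) == 1) {
    named_params(pr)
  } else if (is.numeric(unlist(pr)) && length(unlist(pr)) %in% c(11, 12)) {
    params_from_vector(unlist(pr))
  } else {
    stop("config field 'params' must be a fixture name or an 11-vector")
  }

  se <- default_or(raw, "search", list())
  check_keys(se, c("n_candidates", "temperature", "refine", "refine_points",
                   "n_hues", "n_radii", "s_lattice_max", "tol", "max_iter"),
             "search")
  search <- search_config(
    n_candidates = default_or(se, "n_candidates", 41),
    temperature = default_or(se, "temperature", if (d == 1) 0.01 else 0.002),
    refine = default_or(se, "refine", TRUE),
    refine_points = default_or(se, "refine_points", if (d == 1) 9 else 5),
    n_hues = default_or(se, "n_hues", 12),
    n_radii = default_or(se, "n_radii", 4),
    s_lattice_max = default_or(se, "s_lattice_max", 0.96),
    tol = default_or(se, "tol", 1e-3),
    max_iter = default_or(se, "max_iter", 100))

  merged <- list(
    setting = setting, seed = seed,
    grid = list(nx = grid$nx, ny = grid$ny, spacing = grid$h, nc = grid$nc,
                boundary = grid$boundary),
    stimulus = list(stripe_width = stimulus$stripe_width,
                    n_pairs = stimulus$n_pairs,
                    c_test = format_color(stimulus$c_test),
                    patch_half_width = stimulus$patch_half_width,
                    surround_half_width = stimulus$surround_half_width,
                    test_surround = sur_spec),
    params = if (is.character(pr) && length(pr) == 1) pr else
      as.numeric(params)[1:11],
    search = unclass(search))

  structure(list(setting = setting, seed = seed, grid = grid,
                 stimulus = stimulus, params = params, search = search,
                 raw = merged),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config, setting", x$setting, "seed", x$seed, "\n")
  print(x$grid)
  invisible(x)
}

#' Write run metadata alongside an output file
#'
#' Every CLI run writes a JSON sidecar capturing the materialized config,
#' the seed and solver diagnostics, sufficient to reproduce the run.
#'
#' @param config a `run_config`.
#' @param path output path of the main artifact; the sidecar is
#'   `<path>.meta.json`.
#' @param extra named list of additional metadata (iterations, residuals...).
#' @return the sidecar path, invisibly.
#' @export
write_run_metadata <- function(config, path, extra = list()) {
  meta <- c(list(package = "cnfield",
                 version = as.character(utils::packageVersion("cnfield")),
                 config = config$raw), extra)
  out <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}
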