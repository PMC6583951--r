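#' Synthesize a matching dataset from known parameters
#'
#' Runs the matching emulation under `q_true` for each trial and records the
#' predicted match plus isotropic Gaussian observation noise (clipped back to
#' the color domain) as the observed matched color. Used for
#' parameter-recovery studies of the regression.
#'
#' @param q_true the generating `cnf_params`.
#' @param trials list of [matching_trial()] objects (observed slots are
#'   overwritten).
#' @param grid a `domain_grid`.
#' @param noise_sd standard deviation of the observation noise per color
#'   axis (0 for noiseless data).
#' @param seed integer seed making the noise reproducible.
#' @param search a [search_config()].
#' @return a matching dataset: data frame with columns `trial_id`,
#'   `pattern_id`, `c_test_*`, `c_match_*`, `setting`, with the trial list
#'   (observed filled in) as attribute `"trials"` and the generating
#'   parameters as attribute `"q_true"`.
#' @export
synthesize_matching_dataset <- function(q_true, trials, grid, noise_sd = 0,
                                        seed = 1,
                                        search = search_config()) {
  stopifnot(noise_sd >= 0)
  if (any(vapply(trials, function(t) !is.null(t$observed), NA))) {
    stop("trials already carry observed matches")
  }
  tab <- run_experiment(trials, q_true, grid, search)
  d <- grid$d
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(trials) * d, sd = noise_sd),
                  ncol = d)
  setting <- if (d == 1) "ms1d" else "hsl2d"
  out <- data.frame(trial_id = seq_along(trials),
                    pattern_id = tab$id, stringsAsFactors = FALSE)
  for (k in seq_len(d)) {
    out[[paste0("c_test_", k)]] <- tab[[paste0("c_test_", k)]]
  }
  obs <- matrix(NA_real_, nrow = length(trials), ncol = d)
  for (i in seq_along(trials)) {
    o <- vapply(seq_len(d), function(k) tab[[paste0("c_pred_", k)]][i], 0) +
      noise[i, ]
    o <- clip_to_domain(o, d)
    obs[i, ] <- o
    trials[[i]]$observed <- o
  }
  for (k in seq_len(d)) out[[paste0("c_match_", k)]] <- obs[, k]
  out$setting <- setting
  attr(out, "trials") <- trials
  attr(out, "q_true") <- q_true
  out
}

# Clip a color back into the admissible domain.
clip_to_domain <- function(x, d) {
  if (d == 1) {
    pmin(pmax(x, -2), 2)
  } else {
    nr <- sqrt(sum(x^2))
    if (nr > 1) x / nr else x
  }
}

dataset_columns <- function(d) {
  c("trial_id", "pattern_id", paste0("c_test_", seq_len(d)),
    paste0("c_match_", seq_len(d)), "setting")
}

#' Write / read a matching dataset as CSV
#'
#' The CSV schema has columns `trial_id`, `pattern_id`, `c_test_1`
#' (`, c_test_2` in the 2D setting), `c_match_1` (`, c_match_2`), `setting`
#' (`ms1d` or `hsl2d`); header required, `.` decimal separator, UTF-8.
#' The round trip is lossless (floats at full precision) and preserves row
#' order.
#'
#' @param dataset a matching dataset data frame.
#' @param path file path.
#' @return `read_matching_dataset` returns the dataset data frame;
#'   `write_matching_dataset` returns `path` invisibly.
#' @export
write_matching_dataset <- function(dataset, path) {
  d <- if ("c_test_2" %in% names(dataset)) 2 else 1
  cols <- dataset_columns(d)
  missing <- setdiff(cols, names(dataset))
  if (length(missing)) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- dataset[cols]
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- sprintf("%.17g", out[[nm]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matching_dataset
#' @export
read_matching_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (nrow(raw) == 0) {
    if (!all(c("trial_id", "setting") %in% names(raw))) {
      stop("empty dataset must still carry the schema header")
    }
    return(raw)
  }
  setting <- unique(raw$setting)
  if (length(setting) != 1 || !setting %in% c("ms1d", "hsl2d")) {
    stop("dataset setting must be uniformly 'ms1d' or 'hsl2d'")
  }
  d <- if (setting == "ms1d") 1 else 2
  cols <- dataset_columns(d)
  missing <- setdiff(cols, names(raw))
  if (length(missing)) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "))
  }
  extra_dim <- intersect(c("c_test_2", "c_match_2")[rep(d == 1, 2)], names(raw))
  if (d == 1 && length(extra_dim)) {
    stop("1D (ms1d) dataset carries 2D color column(s): ",
         paste(extra_dim, collapse = ", "))
  }
  num_cols <- grep("^c_(test|match)_", cols, value = TRUE)
  for (nm in num_cols) {
    v <- raw[[nm]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    if (any(is.na(v))) {
      stop("non-numeric or missing values in column ", nm, " (rows ",
           paste(which(is.na(v)), collapse = ", "), ")")
    }
    raw[[nm]] <- v
  }
  raw$pattern_id <- as.character(raw$pattern_id)
  raw[cols]
}

#' Rebuild matching trials from a dataset table
#'
#' For `ms1d` datasets the `pattern_id` column indexes the eight canonical
#' striped patterns (0..7); for `hsl2d` it is ignored and the default
#' square-in-surround geometry is used.
#'
#' @param dataset a matching dataset data frame.
#' @param stripe_width,n_pairs striped geometry (1D setting).
#' @param test_surround,patch_half_width,surround_half_width square geometry
#'   (2D setting).
#' @return list of [matching_trial()] objects with observed matches filled.
#' @export
dataset_trials <- function(dataset, stripe_width = 4, n_pairs = 4,
                           test_surround = hsl_to_disk(60, 0.5),
                           patch_half_width = 0.5,
                           surround_half_width = 0.8) {
  pre <- attr(dataset, "trials")
  if (!is.null(pre)) return(pre)
  if (nrow(dataset) == 0) return(list())
  setting <- dataset$setting[1]
  if (setting == "ms1d") {
    lapply(seq_len(nrow(dataset)), function(i) {
      pats <- enumerate_ms_patterns(dataset$c_test_1[i],
                                    stripe_width = stripe_width,
                                    n_pairs = n_pairs)
      pid <- as.character(dataset$pattern_id[i])
      if (!pid %in% names(pats)) {
        stop("row ", i, ": unknown ms1d pattern_id ", pid)
      }
      matching_trial(pats[[pid]], dataset$c_test_1[i],
                     observed = dataset$c_match_1[i], id = pid)
    })
  } else {
    lapply(seq_len(nrow(dataset)), function(i) {
      ct <- c(dataset$c_test_1[i], dataset$c_test_2[i])
      pat <- square_surround(patch_color = ct,
                             surround_color = test_surround,
                             patch_half_width = patch_half_width,
                             surround_half_width = surround_half_width)
      matching_trial(pat, ct,
                     observed = c(dataset$c_match_1[i], dataset$c_match_2[i]),
                     id = dataset$pattern_id[i])
    })
  }
}
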