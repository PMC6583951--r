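#' Matching-prediction energy of a parameter vector
#'
#' The regression objective: the sum over trials of the squared distance
#' between the model-predicted matching color under `q` and the observed
#' matching color, `E(q) = sum_i |c_pred_i(q) - c_match_i|^2`. The
#' evaluation is a pure function of `(q, trials, grid, search)`. If any
#' trial involves a non-converged steady state the energy for that `q` is
#' reported as a large finite penalty with a flag, so an optimizer retreats
#' instead of crashing.
#'
#' @param q a `cnf_params` object.
#' @param trials list of [matching_trial()] objects with observed matches.
#' @param grid a `domain_grid`.
#' @param search a [search_config()].
#' @param penalty value returned when a steady state fails to converge.
#' @return the energy, with attributes `residuals` (per-trial squared
#'   errors) and `penalized` (logical).
#' @export
matching_energy <- function(q, trials, grid, search = search_config(),
                            penalty = 1e6) {
  stopifnot(length(trials) >= 1)
  if (any(vapply(trials, function(t) is.null(t$observed), NA))) {
    stop("all trials must carry observed matches")
  }
  tab <- suppressWarnings(run_experiment(trials, q, grid, search))
  if (!all(tab$converged)) {
    return(structure(penalty, residuals = rep(NA_real_, length(trials)),
                     penalized = TRUE))
  }
  d <- grid$d
  res <- numeric(length(trials))
  for (i in seq_along(trials)) {
    pred <- vapply(seq_len(d), function(k) tab[[paste0("c_pred_", k)]][i], 0)
    res[i] <- sum((pred - trials[[i]]$observed)^2)
  }
  structure(sum(res), residuals = res, penalized = FALSE)
}

#' Default box bounds around a starting parameter vector
#'
#' @param q0 a `cnf_params` object.
#' @param factor half-width of the box as a multiplicative factor.
#' @return list with numeric vectors `lower` and `upper` (length 11, in the
#'   canonical parameter order; `tau` stays fixed).
#' @export
default_bounds <- function(q0, factor = 0.5) {
  v <- as.numeric(q0)[1:11]
  list(lower = v * (1 - factor), upper = v * (1 + factor))
}

#' Fit the model parameters to a matching dataset
#'
#' Minimizes [matching_energy()] with a bounded derivative-free
#' Nelder-Mead simplex, restarted from the incumbent (with a small seeded
#' jitter) while evaluation budget remains. Box bounds are enforced through
#' a logistic reparameterization, so every proposal is feasible by
#' construction; proposals violating the structural constraint `mu > nu`
#' are rejected with a penalty rather than clipped. The final energy is
#' recomputed independently of the optimizer's bookkeeping.
#'
#' @param dataset a matching dataset (data frame, see
#'   [synthesize_matching_dataset()] / [read_matching_dataset()]), or a list
#'   of trials with observed matches.
#' @param q0 starting `cnf_params` (must satisfy the bounds).
#' @param grid the `domain_grid` to emulate matching on.
#' @param bounds list with `lower` and `upper` 11-vectors
#'   (default: [default_bounds()] around `q0`).
#' @param budget maximum number of energy evaluations.
#' @param seed integer seed (restart jitter); recorded in the result.
#' @param search a [search_config()].
#' @return an object of class `cnf_fit`: `q_hat`, `energy` (recomputed),
#'   `trace` (best-so-far energy per evaluation), `residuals` (per-trial
#'   squared errors at `q_hat`), `evaluations`, `seed`, `bounds`.
#' @export
fit_params <- function(dataset, q0, grid, bounds = default_bounds(q0),
                       budget = 500, seed = 1,
                       search = search_config()) {
  trials <- if (is.data.frame(dataset)) dataset_trials(dataset) else dataset
  stopifnot(length(trials) >= 1, budget >= 1)
  lower <- bounds$lower
  upper <- bounds$upper
  stopifnot(length(lower) == 11, length(upper) == 11, all(upper > lower))
  v0 <- as.numeric(q0)[1:11]
  if (any(v0 < lower) || any(v0 > upper)) {
    stop("q0 lies outside the bounds")
  }
  # logistic map R -> (lower, upper), elementwise
  to_q <- function(z) lower + (upper - lower) / (1 + exp(-z))
  to_z <- function(v) {
    p <- (v - lower) / (upper - lower)
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    log(p / (1 - p))
  }
  n_eval <- 0L
  best_energy <- Inf
  best_v <- v0
  worst_valid <- 0
  trace <- numeric(0)
  objective <- function(z) {
    if (n_eval >= budget) stop(structure(class = c("budget_exhausted",
                                                   "error", "condition"),
                                         list(message = "budget", call = NULL)))
    v <- to_q(z)
    n_eval <<- n_eval + 1L
    e <- if (v[5] <= v[6]) {  # mu <= nu: structurally invalid, reject
      max(10 * worst_valid, 1e6)
    } else {
      q <- params_from_vector(v)
      val <- matching_energy(q, trials, grid, search,
                             penalty = max(10 * worst_valid, 1e6))
      if (!attr(val, "penalized")) worst_valid <<- max(worst_valid, val)
      as.numeric(val)
    }
    if (e < best_energy) {
      best_energy <<- e
      best_v <<- v
    }
    trace[n_eval] <<- best_energy
    e
  }
  set.seed(seed)
  z <- to_z(v0)
  while (n_eval < budget) {
    res <- tryCatch(
      stats::optim(z, objective, method = "Nelder-Mead",
                   control = list(maxit = 10 * budget, reltol = 1e-10)),
      budget_exhausted = function(e) NULL)
    if (is.null(res)) break
    if (n_eval >= budget) break
    # restart from the incumbent with a small seeded jitter
    z <- to_z(best_v) + stats::rnorm(11, sd = 0.05)
  }
  if (!is.finite(best_energy)) stop("no valid energy evaluation within budget")
  q_hat <- params_from_vector(best_v)
  final <- matching_energy(q_hat, trials, grid, search)
  if (abs(as.numeric(final) - best_energy) > 1e-9 * max(1, best_energy)) {
    warning("recomputed energy differs from optimizer record by ",
            signif(abs(as.numeric(final) - best_energy), 3))
  }
  structure(list(q_hat = q_hat, energy = as.numeric(final),
                 residuals = attr(final, "residuals"),
                 trace = trace, evaluations = n_eval, seed = seed,
                 bounds = bounds),
            class = "cnf_fit")
}

#' @export
print.cnf_fit <- function(x, ...) {
  cat(sprintf("cnf_fit: energy %.6g after %d evaluations (seed %d)\n",
              x$energy, x$evaluations, x$seed))
  print(x$q_hat)
  invisible(x)
}
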