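#' Model parameter vector
#'
#' The neural field is governed by eleven scalars
#' `q = (mu_c, nu_c, alpha_c, beta_c, mu, nu, alpha, beta, mu_h, sigma_h, gamma)`:
#' amplitudes and widths of the two color-kernel Gaussians (`mu_c`, `nu_c`,
#' `alpha_c`, `beta_c`), amplitudes and widths of the spatial
#' difference-of-Gaussians (`mu`, `nu`, `alpha`, `beta`), amplitude and width
#' of the Gaussian color input (`mu_h`, `sigma_h`), and the sigmoid gain
#' `gamma`. The time constant `tau` is fixed to 1 (time is measured in units
#' of it). Local spatial excitation requires `mu > nu`; all widths and `gamma`
#' are positive, all amplitudes non-negative. Amplitudes are peak heights: the
#' Gaussians are not normalized to unit mass.
#'
#' @param mu_c,nu_c amplitudes of the attractive / opponent-repulsive color
#'   Gaussians (dimensionless).
#' @param alpha_c,beta_c widths of the color Gaussians (opponent-color units).
#' @param mu,nu amplitudes of the spatial DOG center / surround.
#' @param alpha,beta widths of the spatial DOG center / surround
#'   (cortical length units).
#' @param mu_h amplitude of the color input kernel.
#' @param sigma_h width of the color input kernel.
#' @param gamma sigmoid gain; the maximal slope of the activation is
#'   `gamma / 4`.
#' @param tau time constant (fixed at 1).
#' @return an object of class `cnf_params`.
#' @seealso [named_params()] for the regressed vectors shipped with the
#'   package.
#' @export
model_params <- function(mu_c, nu_c, alpha_c, beta_c, mu, nu, alpha, beta,
                         mu_h, sigma_h, gamma, tau = 1) {
  q <- list(mu_c = mu_c, nu_c = nu_c, alpha_c = alpha_c, beta_c = beta_c,
            mu = mu, nu = nu, alpha = alpha, beta = beta,
            mu_h = mu_h, sigma_h = sigma_h, gamma = gamma, tau = tau)
  for (nm in names(q)) {
    v <- q[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter ", nm, " must be a finite scalar")
    }
  }
  if (q$mu <= q$nu) {
    stop("local spatial excitation requires mu > nu (got mu = ", mu,
         ", nu = ", nu, ")")
  }
  for (nm in c("alpha_c", "beta_c", "alpha", "beta", "sigma_h", "gamma", "tau")) {
    if (q[[nm]] <= 0) stop("parameter ", nm, " must be positive")
  }
  for (nm in c("mu_c", "nu_c", "mu", "nu", "mu_h")) {
    if (q[[nm]] < 0) stop("amplitude ", nm, " must be non-negative")
  }
  structure(q, class = "cnf_params")
}

#' @export
print.cnf_params <- function(x, ...) {
  cat("Color neural field parameters q:\n")
  v <- as.numeric(x)
  names(v) <- c("mu_c", "nu_c", "alpha_c", "beta_c", "mu", "nu", "alpha",
                "beta", "mu_h", "sigma_h", "gamma", "tau")
  print(v, ...)
  invisible(x)
}

#' @export
as.numeric.cnf_params <- function(x, ...) {
  unlist(x[c("mu_c", "nu_c", "alpha_c", "beta_c", "mu", "nu", "alpha",
             "beta", "mu_h", "sigma_h", "gamma", "tau")], use.names = FALSE)
}

#' Build a parameter object from the 11-vector form
#'
#' @param v numeric vector `(mu_c, nu_c, alpha_c, beta_c, mu, nu, alpha,
#'   beta, mu_h, sigma_h, gamma)`, optionally with `tau` as a 12th entry.
#' @return a `cnf_params` object.
#' @export
params_from_vector <- function(v) {
  stopifnot(is.numeric(v), length(v) %in% c(11, 12))
  model_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8], v[9], v[10],
               v[11], tau = if (length(v) == 12) v[12] else 1)
}

# Regressed parameter vectors for the published fits. Immutable fixtures.
.named_param_table <- list(
  q_MC     = c(0.60, 0.69, 0.30, 0.40, 4.42, 1.82, 0.58, 8.35, 0.47, 0.30, 1.80),
  q_AZ     = c(0.60, 0.69, 0.31, 0.40, 4.42, 1.81, 0.60, 8.35, 0.47, 0.30, 1.80),
  q_nonlin = c(0.42, 0.71, 0.63, 1.16, 4.43, 1.72, 0.56, 6.35, 0.47, 0.30, 1.80),
  q_HSL    = c(0.73, 0.15, 0.52, 0.68, 4.41, 1.84, 0.51, 8.35, 0.47, 0.30, 1.80)
)

#' Named regressed parameter vectors
#'
#' Four parameter vectors obtained by regressing the model to published and
#' personal matching data ship with the package: `q_MC` and `q_AZ` (fits to
#' the two observers of the striped-pattern matching study), `q_nonlin` (fit
#' to the nonlinear shift-versus-test-chromaticity data), and `q_HSL` (fit to
#' the chromatic-disk vector field of shifts).
#'
#' @param name one of `"q_MC"`, `"q_AZ"`, `"q_nonlin"`, `"q_HSL"`.
#' @return a `cnf_params` object.
#' @examples
#' named_params("q_MC")
#' @export
named_params <- function(name) {
  name <- match.arg(name, names(.named_param_table))
  params_from_vector(.named_param_table[[name]])
}

#' Read a parameter vector from a JSON file
#'
#' Accepts either a JSON array of 11 (or 12, with `tau`) numbers in the
#' canonical order, or an object with the named fields of [model_params()].
#'
#' @param path path to the JSON file.
#' @return a `cnf_params` object.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.numeric(x)) {
    params_from_vector(x)
  } else if (is.list(x)) {
    need <- c("mu_c", "nu_c", "alpha_c", "beta_c", "mu", "nu", "alpha",
              "beta", "mu_h", "sigma_h", "gamma")
    missing <- setdiff(need, names(x))
    if (length(missing)) {
      stop("parameter file missing field(s): ", paste(missing, collapse = ", "))
    }
    do.call(model_params, x[c(need, intersect("tau", names(x)))])
  } else {
    stop("unrecognized parameter file format")
  }
}
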