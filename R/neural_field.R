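#' Sigmoid activation function
#'
#' The logistic activation `F(x) = 1 / (1 + exp(-gamma x))`, strictly
#' increasing from 0 to 1, with maximal slope `F'(0) = gamma / 4`.
#'
#' @param x numeric vector or array.
#' @param q a `cnf_params` object (only `gamma` is used) or a scalar gain.
#' @return values in `(0, 1)`, same shape as `x`.
#' @export
sigmoid <- function(x, q) {
  gamma <- if (inherits(q, "cnf_params")) q$gamma else q
  1 / (1 + exp(-gamma * x))
}

#' Spatial difference-of-Gaussians connectivity kernel
#'
#' The Mexican-hat weight `g(r) = mu exp(-|r|^2 / 2 alpha^2) -
#' nu exp(-|r|^2 / 2 beta^2)` carrying the influence of spatially neighboring
#' hypercolumns: excitatory at short range (`g(0) = mu - nu > 0`), inhibitory
#' at intermediate range when `alpha < beta`.
#'
#' @param r a 2-vector, or a matrix with one offset per row.
#' @param q a `cnf_params` object.
#' @return kernel value(s).
#' @export
spatial_kernel <- function(r, q) {
  r2 <- if (is.matrix(r)) rowSums(r^2) else sum(r^2)
  q$mu * exp(-r2 / (2 * q$alpha^2)) - q$nu * exp(-r2 / (2 * q$beta^2))
}

#' Opponency color kernel
#'
#' `f(c, c') = mu_c exp(-|c - c'|^2 / 2 alpha_c^2) -
#' nu_c exp(-|c + c'|^2 / 2 beta_c^2)`: a difference of Gaussians, one
#' centered at `c` (attraction toward similar colors) and one at the opponent
#' `-c` (repulsion from opponent colors). Symmetric in its two arguments.
#'
#' @param c,c2 opponent colors of equal dimension.
#' @param q a `cnf_params` object.
#' @return kernel value.
#' @export
color_kernel <- function(c, c2, q) {
  if (length(c) != length(c2)) stop("color dimension mismatch")
  q$mu_c * exp(-sum((c - c2)^2) / (2 * q$alpha_c^2)) -
    q$nu_c * exp(-sum((c + c2)^2) / (2 * q$beta_c^2))
}

#' Gaussian color-input kernel
#'
#' `h(c) = mu_h exp(-|c|^2 / 2 sigma_h^2)`, the tuning profile with which a
#' viewed color drives the neural masses; maximal (`= mu_h`) at zero offset.
#'
#' @param c opponent color offset (vector, or matrix with one offset per row).
#' @param q a `cnf_params` object.
#' @return kernel value(s).
#' @export
input_kernel <- function(c, q) {
  c2 <- if (is.matrix(c)) rowSums(c^2) else sum(c^2)
  q$mu_h * exp(-c2 / (2 * q$sigma_h^2))
}

#' Lift a cortical image to the color input field
#'
#' `H(r, c) = h(c - I(r))`: each spatial node drives most strongly the neural
#' masses tuned to colors closest to the viewed color `I(r)`. Masked color
#' nodes (outside the disk in the 2D setting) receive zero input.
#'
#' @param image a `cortical_image`.
#' @param q a `cnf_params` object.
#' @return an `input_field`: array over `(nx, ny, color nodes)` with the grid
#'   attached.
#' @export
build_input <- function(image, q) {
  grid <- image$grid
  ns <- grid$nx * grid$ny
  imat <- matrix(image$values, nrow = ns, ncol = grid$d)
  cc <- grid$color_coords
  # squared distances between every color node and every image color
  d2 <- outer(rowSums(cc^2), rowSums(imat^2), `+`) - 2 * cc %*% t(imat)
  H <- q$mu_h * exp(-pmax(d2, 0) / (2 * q$sigma_h^2))  # n_color x ns
  H[!color_mask(grid), ] <- 0
  structure(list(values = unflatten_field(t(H), grid), grid = grid),
            class = "input_field")
}

# ---- convolution machinery --------------------------------------------------

# FFT of a 1D Gaussian kernel sampled on the axis offset grid, premultiplied
# by the node spacing (Riemann weight). Zero boundary pads to length 2n and
# truncates the kernel at the domain size; periodic uses minimum-image
# offsets at length n.
axis_kernel_fft <- function(n, h, sigma, boundary) {
  if (boundary == "zero") {
    N <- 2L * n
    kv <- numeric(N)
    g <- exp(-((0:(n - 1)) * h)^2 / (2 * sigma^2))
    kv[1:n] <- g
    if (n > 1) kv[N + 1 - (1:(n - 1))] <- g[2:n]
    list(N = N, n = n, fft = stats::fft(kv * h))
  } else {
    offs <- 0:(n - 1)
    offs <- ifelse(offs > n / 2, offs - n, offs)
    g <- exp(-((offs) * h)^2 / (2 * sigma^2))
    list(N = n, n = n, fft = stats::fft(g * h))
  }
}

# Convolve an array along one axis with a precomputed kernel FFT.
conv_axis <- function(A, axis, kf) {
  d <- dim(A)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  M <- matrix(aperm(A, perm), nrow = d[axis])
  if (kf$N > kf$n) M <- rbind(M, matrix(0, kf$N - kf$n, ncol(M)))
  Y <- Re(stats::mvfft(stats::mvfft(M) * kf$fft, inverse = TRUE)) / kf$N
  Y <- Y[seq_len(kf$n), , drop = FALSE]
  aperm(array(Y, dim = d[perm]), order(perm))
}

#' Precomputed connectivity operator for a (parameters, grid) pair
#'
#' Caches the axis-kernel FFTs used by the convolution form of the
#' connectivity, `omega * a = g *_Omega (f1 *_C a - Sym (f2 *_C a))`. Build
#' it once and reuse it across steady-state solves on the same grid.
#'
#' @param q a `cnf_params` object.
#' @param grid a `domain_grid`.
#' @return an object of class `field_operator`.
#' @export
field_operator <- function(q, grid) {
  stopifnot(inherits(q, "cnf_params"), inherits(grid, "domain_grid"))
  op <- list(
    q = q, grid = grid,
    sxa = axis_kernel_fft(grid$nx, grid$h, q$alpha, grid$boundary),
    sya = axis_kernel_fft(grid$ny, grid$h, q$alpha, grid$boundary),
    sxb = axis_kernel_fft(grid$nx, grid$h, q$beta, grid$boundary),
    syb = axis_kernel_fft(grid$ny, grid$h, q$beta, grid$boundary),
    ca = axis_kernel_fft(grid$nc, grid$hc, q$alpha_c, "zero"),
    cb = axis_kernel_fft(grid$nc, grid$hc, q$beta_c, "zero")
  )
  structure(op, class = "field_operator")
}

# Separable Gaussian convolution over the color axes (3, and 4 in 2D).
conv_color <- function(A, kf, grid) {
  B <- conv_axis(A, 3L, kf)
  if (grid$d == 2) B <- conv_axis(B, 4L, kf)
  B
}

# Separable Gaussian convolution over the spatial axes (1, 2).
conv_spatial <- function(A, kfx, kfy) {
  conv_axis(conv_axis(A, 1L, kfx), 2L, kfy)
}

#' Apply the connectivity operator to an activity field
#'
#' Computes the lateral input `omega * a`, the double integral of
#' `g(r - r') f(c, c') a(r', c')` over space and color with Riemann cell
#' weights. The default path evaluates the convolution form
#' `g *_Omega (f1 *_C a - Sym (f2 *_C a))` with FFTs (kernels truncated at
#' the domain size; zero-padded or periodic spatial boundary per the grid);
#' `method = "direct"` evaluates the discretized double sum with dense
#' matrices and serves as the independent reference.
#'
#' @param a an `activity_field`, or a raw array over the grid.
#' @param q a `cnf_params` object.
#' @param grid the `domain_grid` (taken from `a` if it is an
#'   `activity_field`).
#' @param method `"fft"` (default) or `"direct"`.
#' @param op optional precomputed [field_operator()] (FFT path).
#' @return array of the same shape as the activity values.
#' @export
apply_connectivity <- function(a, q, grid = NULL, method = c("fft", "direct"),
                               op = NULL) {
  method <- match.arg(method)
  if (inherits(a, "activity_field")) {
    if (is.null(grid)) grid <- a$grid
    a <- a$values
  }
  if (is.null(grid)) stop("grid must be supplied for raw arrays")
  if (!identical(dim(a), field_dim(grid))) {
    stop("activity dimensions do not match the grid")
  }
  if (method == "direct") {
    return(apply_connectivity_direct(a, q, grid))
  }
  if (is.null(op)) op <- field_operator(q, grid)
  mask <- color_mask(grid)
  if (!all(mask)) {
    am <- flatten_field(a, grid)
    am[, !mask] <- 0
    a <- unflatten_field(am, grid)
  }
  b1 <- q$mu_c * conv_color(a, op$ca, grid)
  b2 <- q$nu_c * conv_color(a, op$cb, grid)
  u <- b1 - sym_flip(b2, grid)
  out <- q$mu * conv_spatial(u, op$sxa, op$sya) -
    q$nu * conv_spatial(u, op$sxb, op$syb)
  if (!all(mask)) {
    om <- flatten_field(out, grid)
    om[, !mask] <- 0
    out <- unflatten_field(om, grid)
  }
  out
}

# Dense double-sum evaluation of omega * a (reference implementation,
# O(N^2); meant for small grids).
apply_connectivity_direct <- function(a, q, grid) {
  xy <- as.matrix(expand.grid(x = grid$x, y = grid$y))
  if (grid$boundary == "periodic") {
    Lx <- grid$nx * grid$h
    Ly <- grid$ny * grid$h
    dx <- outer(xy[, 1], xy[, 1], `-`)
    dy <- outer(xy[, 2], xy[, 2], `-`)
    dx <- dx - Lx * round(dx / Lx)
    dy <- dy - Ly * round(dy / Ly)
    D2 <- dx^2 + dy^2
  } else {
    D2 <- outer(rowSums(xy^2), rowSums(xy^2), `+`) - 2 * xy %*% t(xy)
    D2 <- pmax(D2, 0)
  }
  G <- (q$mu * exp(-D2 / (2 * q$alpha^2)) -
          q$nu * exp(-D2 / (2 * q$beta^2))) * grid$h^2
  cc <- grid$color_coords
  s2 <- rowSums(cc^2)
  Dm2 <- outer(s2, s2, `+`) - 2 * cc %*% t(cc)   # |c - c'|^2
  Dp2 <- outer(s2, s2, `+`) + 2 * cc %*% t(cc)   # |c + c'|^2
  Fm <- (q$mu_c * exp(-pmax(Dm2, 0) / (2 * q$alpha_c^2)) -
           q$nu_c * exp(-pmax(Dp2, 0) / (2 * q$beta_c^2))) * grid$hc^grid$d
  mask <- color_mask(grid)
  Fm[, !mask] <- 0
  Fm[!mask, ] <- 0
  am <- flatten_field(a, grid)
  am[, !mask] <- 0
  unflatten_field(G %*% am %*% t(Fm), grid)
}

# ---- dynamics ---------------------------------------------------------------

new_activity_field <- function(values, grid, n_iter = NA_integer_,
                               converged = NA, residual = NA_real_,
                               sup_changes = numeric(0)) {
  structure(list(values = values, grid = grid, n_iter = n_iter,
                 converged = converged, residual = residual,
                 sup_changes = sup_changes),
            class = "activity_field")
}

#' @export
print.activity_field <- function(x, ...) {
  cat(sprintf(
    "activity_field on %dx%d x %d^%d grid; range (%.4f, %.4f)",
    x$grid$nx, x$grid$ny, x$grid$nc, x$grid$d,
    min(x$values), max(x$values)))
  if (!is.na(x$n_iter)) {
    cat(sprintf("; %d iterations, %s (residual %.2e)",
                x$n_iter, if (isTRUE(x$converged)) "converged" else
                  "NOT converged", x$residual))
  }
  cat("\n")
  invisible(x)
}

# Uniform initial condition a0 = 1/2 = F(0), the symmetric default.
default_initial_condition <- function(grid) {
  array(0.5, dim = field_dim(grid))
}

sup_diff <- function(a, b, grid) {
  mask <- color_mask(grid)
  if (all(mask)) return(max(abs(a - b)))
  max(abs(flatten_field(a, grid)[, mask, drop = FALSE] -
            flatten_field(b, grid)[, mask, drop = FALSE]))
}

#' Evolve the neural field for a fixed number of Euler steps
#'
#' Integrates `tau da/dt = -a + F(omega * a + H)` with the explicit Euler
#' scheme `a_{n+1} = a_n + (dt/tau) (-a_n + F(omega * a_n + H))`. For
#' `dt = tau = 1` this is the fixed-point map `a -> F(omega * a + H)`.
#' Iterates started in `(0, 1)` remain in `(0, 1)`.
#'
#' @param image a `cortical_image` (the static stimulus).
#' @param q a `cnf_params` object.
#' @param a0 initial activity array (default: uniform 0.5).
#' @param dt Euler step, in `(0, 1]` (time unit is `tau`).
#' @param n_steps number of steps.
#' @param keep_trajectory if `TRUE`, also return every iterate.
#' @return an `activity_field` holding the final iterate, with the sup-norm
#'   change per step in `$sup_changes`; if `keep_trajectory`, the iterates
#'   are attached as attribute `"trajectory"` (list of arrays, including
#'   `a0`).
#' @export
evolve <- function(image, q, a0 = NULL, dt = 1, n_steps = 15,
                   keep_trajectory = FALSE) {
  grid <- image$grid
  if (dt <= 0 || dt > 1) stop("dt must lie in (0, 1]")
  if (is.null(a0)) a0 <- default_initial_condition(grid)
  if (inherits(a0, "activity_field")) a0 <- a0$values
  if (any(a0 <= 0) || any(a0 >= 1)) stop("a0 must lie strictly in (0, 1)")
  op <- field_operator(q, grid)
  H <- build_input(image, q)$values
  a <- a0
  changes <- numeric(n_steps)
  traj <- if (keep_trajectory) vector("list", n_steps + 1)
  if (keep_trajectory) traj[[1]] <- a0
  for (i in seq_len(n_steps)) {
    fx <- sigmoid(apply_connectivity(a, q, grid, op = op) + H, q)
    anew <- a + (dt / q$tau) * (fx - a)
    changes[i] <- sup_diff(anew, a, grid)
    a <- anew
    if (keep_trajectory) traj[[i + 1]] <- a
  }
  out <- new_activity_field(a, grid, n_iter = n_steps, converged = NA,
                            residual = changes[n_steps],
                            sup_changes = changes)
  if (keep_trajectory) attr(out, "trajectory") <- traj
  out
}

#' Steady state of the neural field for a static stimulus
#'
#' Iterates the `dt = 1` fixed-point map `a -> F(omega * a + H)` from the
#' default initial condition until the sup-norm change between successive
#' iterates falls below `tol`, or `max_iter` is reached. At convergence the
#' fixed-point residual `|a - F(omega * a + H)|_inf` is below `tol` by
#' construction. Non-convergence is flagged, never silent.
#'
#' @param image a `cortical_image`.
#' @param q a `cnf_params` object.
#' @param tol sup-norm convergence tolerance (default `1e-3`).
#' @param max_iter iteration cap (default 100).
#' @param a0 initial activity (default: uniform 0.5).
#' @param op optional precomputed [field_operator()].
#' @return an `activity_field` with fields `n_iter`, `converged`, `residual`
#'   and the per-iteration `sup_changes`.
#' @export
steady_state <- function(image, q, tol = 1e-3, max_iter = 100, a0 = NULL,
                         op = NULL) {
  stopifnot(tol > 0, max_iter >= 1)
  grid <- image$grid
  if (is.null(a0)) a0 <- default_initial_condition(grid)
  if (inherits(a0, "activity_field")) a0 <- a0$values
  if (any(a0 <= 0) || any(a0 >= 1)) stop("a0 must lie strictly in (0, 1)")
  if (is.null(op)) op <- field_operator(q, grid)
  H <- build_input(image, q)$values
  a <- a0
  changes <- numeric(0)
  converged <- FALSE
  i <- 0
  while (i < max_iter) {
    i <- i + 1
    anew <- sigmoid(apply_connectivity(a, q, grid, op = op) + H, q)
    ch <- sup_diff(anew, a, grid)
    changes[i] <- ch
    a <- anew
    if (ch < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("steady_state did not converge in ", max_iter,
            " iterations (last change ", signif(changes[i], 3), ")")
  }
  new_activity_field(a, grid, n_iter = i, converged = converged,
                     residual = changes[i], sup_changes = changes)
}

#' Extract the color sensation at a cortical point
#'
#' The color sensation generated by a stimulus at a cortical point `r0` is
#' the steady-state activity profile of that hypercolumn over color space:
#' the slice `a(r0, .)`, a tabulated function on the (unmasked) color nodes.
#'
#' @param a a converged `activity_field`.
#' @param r0 spatial node index `c(ix, iy)`; default the node nearest the
#'   cortical origin.
#' @return an object of class `color_sensation` with the activity values,
#'   the color node coordinates, `r0`, and the convergence flag.
#' @export
color_sensation <- function(a, r0 = NULL) {
  stopifnot(inherits(a, "activity_field"))
  grid <- a$grid
  if (is.null(r0)) r0 <- grid_center(grid)
  stopifnot(length(r0) == 2, r0[1] >= 1, r0[1] <= grid$nx,
            r0[2] >= 1, r0[2] <= grid$ny)
  if (!isTRUE(a$converged)) {
    warning("extracting a color sensation from a non-converged activity field")
  }
  mask <- color_mask(grid)
  vals <- flatten_field(a$values, grid)[(r0[2] - 1) * grid$nx + r0[1], ]
  structure(list(values = vals[mask],
                 coords = grid$color_coords[mask, , drop = FALSE],
                 r0 = r0, d = grid$d, converged = isTRUE(a$converged)),
            class = "color_sensation")
}

#' @export
print.color_sensation <- function(x, ...) {
  cat(sprintf(
    "color_sensation at node (%d, %d): %d color nodes, range (%.4f, %.4f)%s\n",
    x$r0[1], x$r0[2], length(x$values), min(x$values), max(x$values),
    if (x$converged) "" else " [non-converged]"))
  invisible(x)
}
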