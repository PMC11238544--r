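#' Analytical potentials and static biases
#'
#' Closed-form potentials with exact gradients serve two roles: as ground
#' truth for simulate-then-recover tests (the toy systems identify the CV
#' with the particle coordinate) and as static bias building blocks that can
#' be combined freely with metadynamics (harmonic restraints, walls).
#'
#' All constructors return a `cv_potential` object; `pot_value()` and
#' `pot_grad()` evaluate value and analytic gradient, vectorized over points.
#'
#' @name potentials
NULL

new_potential <- function(spec, ndim, label) {
  structure(c(spec, list(ndim = ndim, label = label)),
            class = "cv_potential")
}

#' @export
print.cv_potential <- function(x, ...) {
  cat(sprintf("cv_potential '%s' (%s, %dD)\n", x$label, x$type, x$ndim))
  invisible(x)
}

#' One-dimensional polynomial potential
#'
#' @param coef numeric coefficients `c0, c1, ...` of `sum c_k s^k`.
#' @return a `cv_potential`.
#' @export
poly1d <- function(coef) {
  new_potential(list(type = "poly1d", coef = as.numeric(coef)), 1L, "poly1d")
}

#' Two-dimensional polynomial potential
#'
#' @param coef numeric matrix with columns (power of s1, power of s2,
#'   coefficient).
#' @param label optional name.
#' @return a `cv_potential`.
#' @export
poly2d <- function(coef, label = "poly2d") {
  coef <- as.matrix(coef)
  stopifnot(ncol(coef) == 3L)
  new_potential(list(type = "poly2d", coef = coef), 2L, label)
}

#' Built-in model potentials
#'
#' `"doublewell2d"` is the two-dimensional double-well polynomial widely used
#' in the enhanced-sampling literature: two basins (global minimum near
#' (-1.88, 0.78), a second minimum ~3.4 energy units higher near
#' (1.78, -0.83)) separated by a barrier of ~15 energy units.
#' `"multiwell1d"` is a one-dimensional profile with several closely spaced
#' wells below s = 0.5 and one metastable well near s = 0.8, confined to
#' roughly [-0.2, 1.2].
#'
#' @param name one of `"doublewell2d"`, `"multiwell1d"`.
#' @return a `cv_potential`.
#' @export
builtin_potential <- function(name = c("doublewell2d", "multiwell1d")) {
  name <- match.arg(name)
  switch(name,
    doublewell2d = poly2d(rbind(
      c(4, 0,  1.35), c(3, 1,  1.90), c(2, 2,  3.93), c(2, 0, -6.44),
      c(1, 3, -1.90), c(1, 1,  5.59), c(1, 0,  1.33), c(0, 4,  1.35),
      c(0, 2, -5.56), c(0, 1,  0.90), c(0, 0, 18.59)), label = "doublewell2d"),
    multiwell1d = multiwell1d())
}

#' One-dimensional multiwell potential
#'
#' A configurable sum of Gaussian wells plus an even-power confining term
#' `conf_k * ((s - conf_c)/conf_s)^conf_p`. The default places four wells
#' below s = 0.5 and one shallower metastable well at s = 0.8.
#'
#' @param depth,center,width per-well Gaussian parameters (depths > 0 give
#'   wells).
#' @param conf_k,conf_c,conf_s,conf_p confining term parameters.
#' @return a `cv_potential`.
#' @export
multiwell1d <- function(depth = c(6, 4.5, 5.5, 4, 3.5),
                        center = c(0.0, 0.15, 0.3, 0.45, 0.8),
                        width = c(0.045, 0.045, 0.045, 0.045, 0.06),
                        conf_k = 8, conf_c = 0.5, conf_s = 0.75,
                        conf_p = 8) {
  stopifnot(length(depth) == length(center), length(center) == length(width),
            all(width > 0), conf_p %% 2 == 0)
  new_potential(list(type = "multiwell1d", depth = as.numeric(depth),
                     center = as.numeric(center), width = as.numeric(width),
                     conf_k = conf_k, conf_c = conf_c, conf_s = conf_s,
                     conf_p = as.integer(conf_p)), 1L, "multiwell1d")
}

#' Harmonic restraint bias
#'
#' `0.5 * sum_a kappa_a (s_a - center_a)^2`; value and gradient vanish at the
#' center.
#'
#' @param center numeric center (length = CV dimension).
#' @param kappa nonnegative spring constant(s), recycled per axis.
#' @return a `cv_potential`.
#' @export
harmonic_bias <- function(center, kappa) {
  center <- as.numeric(center)
  kappa <- rep_len(as.numeric(kappa), length(center))
  stopifnot(all(kappa >= 0))
  new_potential(list(type = "harmonic", center = center, kappa = kappa),
                length(center), "harmonic")
}

#' Wall bias
#'
#' One-sided restraint `kappa * |s_axis - at|^exponent` applied beyond the
#' threshold; exactly zero (value and gradient) on the allowed side.
#'
#' @param axis CV axis the wall acts on (1-based).
#' @param at threshold position.
#' @param side `"upper"` (restrain s > at) or `"lower"`.
#' @param kappa force constant.
#' @param exponent wall exponent (default 2, harmonic wall).
#' @param ndim dimension of the CV space the wall lives in.
#' @return a `cv_potential`.
#' @export
wall_bias <- function(axis, at, side = c("upper", "lower"), kappa,
                      exponent = 2L, ndim = 1L) {
  side <- match.arg(side)
  new_potential(list(type = "wall", axis = as.integer(axis), at = at,
                     side = side, kappa = kappa,
                     exponent = as.integer(exponent)), ndim, "wall")
}

as_points <- function(s, ndim) {
  if (is.matrix(s)) s else matrix(s, ncol = ndim, byrow = length(s) > ndim)
}

#' Evaluate a potential
#'
#' @param pot a `cv_potential`.
#' @param s a point (numeric of length `ndim`) or a matrix of points (one
#'   row each).
#' @return numeric value(s).
#' @export
pot_value <- function(pot, s) {
  cpp_pot_eval(unclass(pot), as_points(s, pot$ndim))$value
}

#' Analytic gradient of a potential
#'
#' @inheritParams pot_value
#' @return gradient matrix (one row per point) or vector for a single point.
#' @export
pot_grad <- function(pot, s) {
  g <- cpp_pot_eval(unclass(pot), as_points(s, pot$ndim))$gradient
  if (!is.matrix(s) && nrow(g) == 1L) drop(g) else g
}

#' Reference free-energy surface on a grid
#'
#' Evaluates the potential at every node and shifts the result so the grid
#' minimum is exactly zero (the FES gauge used throughout).
#'
#' @param pot a `cv_potential`.
#' @param grid a `cv_grid` of matching dimension.
#' @return a `scalar_field`.
#' @export
reference_fes <- function(pot, grid) {
  stopifnot(pot$ndim == grid$ndim)
  v <- pot_value(pot, grid_points(grid))
  scalar_field(grid, v - min(v))
}

#' Gradient of a potential on every grid node
#'
#' @inheritParams reference_fes
#' @return a `vector_field` with the analytic gradient components.
#' @export
gradient_field <- function(pot, grid) {
  stopifnot(pot$ndim == grid$ndim)
  g <- cpp_pot_eval(unclass(pot), grid_points(grid))$gradient
  vector_field(grid, lapply(seq_len(grid$ndim), function(a) g[, a]))
}

# sum of static-bias gradients on the grid (zero field when empty)
static_gradient_field <- function(static_biases, grid) {
  comps <- lapply(seq_len(grid$ndim), function(a) rep(0, n_nodes(grid)))
  total <- vector_field(grid, comps)
  for (b in static_biases) {
    gf <- gradient_field(b, grid)
    for (a in seq_len(grid$ndim))
      total$components[[a]] <- total$components[[a]] + gf$components[[a]]
  }
  total
}
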