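#' Metadynamics parameters
#'
#' @param w0 initial hill height (> 0, energy units).
#' @param sigma per-axis hill width (> 0).
#' @param pace steps between hill deposits (>= 1).
#' @param bias_factor well-tempering factor gamma (> 1), or `NULL` for plain
#'   (non-tempered) metadynamics.
#' @param kT thermal energy used in the well-tempering rule; defaults to the
#'   simulation kT when used inside [run_langevin()].
#' @return a `metad_params` list.
#' @export
metad_params <- function(w0 = 1, sigma = 0.1, pace = 200L,
                         bias_factor = NULL, kT = NULL) {
  stopifnot(w0 > 0, all(sigma > 0), pace >= 1,
            is.null(bias_factor) || bias_factor > 1)
  structure(list(w0 = w0, sigma = as.numeric(sigma),
                 pace = as.integer(pace), bias_factor = bias_factor,
                 kT = kT), class = "metad_params")
}

#' Hills log
#'
#' The time-ordered record of deposited Gaussian hills, plus tempering
#' metadata. Each hill has a center, per-axis width, height and deposit time.
#'
#' @param time strictly increasing deposit times.
#' @param center matrix of hill centers (one row per hill).
#' @param sigma matrix of per-axis widths (> 0).
#' @param height nonnegative hill heights.
#' @param bias_factor gamma (> 1) for well-tempered runs, `NULL` otherwise.
#' @param kT thermal energy of the run.
#' @param pace time between deposits.
#' @return a `hills_log`.
#' @export
hills_log <- function(time, center, sigma, height, bias_factor = NULL,
                      kT = 1, pace = NULL) {
  if (!is.matrix(center)) center <- matrix(center, ncol = 1L)
  if (!is.matrix(sigma)) sigma <- matrix(sigma, nrow = nrow(center),
                                         ncol = ncol(center))
  stopifnot(length(time) == nrow(center), nrow(sigma) == nrow(center),
            length(height) == nrow(center))
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("hill times must be strictly increasing")
  if (any(sigma <= 0)) stop("hill widths must be positive")
  if (any(height < 0)) stop("hill heights must be nonnegative")
  if (!is.null(bias_factor) && bias_factor <= 1)
    stop("bias_factor must exceed 1")
  if (is.null(pace) && length(time) > 1L) pace <- stats::median(diff(time))
  structure(list(hills = list(time = as.numeric(time), center = center,
                              sigma = sigma, height = as.numeric(height)),
                 bias_factor = bias_factor, kT = kT, pace = pace,
                 ndim = ncol(center)), class = "hills_log")
}

#' An empty hills log
#'
#' @param ndim CV dimension.
#' @param kT thermal energy.
#' @return a `hills_log` with no hills (the static-bias limit).
#' @export
empty_hills_log <- function(ndim, kT = 1) {
  hills_log(numeric(0), matrix(numeric(0), 0, ndim),
            matrix(numeric(0), 0, ndim), numeric(0), kT = kT)
}

#' Number of hills in a log
#'
#' @param log a `hills_log`.
#' @return integer count.
#' @export
n_hills <- function(log) length(log$hills$time)

#' @export
print.hills_log <- function(x, ...) {
  cat(sprintf("hills_log: %d hills, %dD, %s\n", n_hills(x), x$ndim,
              if (is.null(x$bias_factor)) "plain MetaD"
              else sprintf("well-tempered (gamma = %g)", x$bias_factor)))
  invisible(x)
}

#' Metadynamics bias value at arbitrary points
#'
#' Sums the deposited hills (with `time <= upto_time`) at the given CV
#' point(s), using minimum-image displacements on periodic axes.
#'
#' @param log a `hills_log`.
#' @param s a point or matrix of points.
#' @param grid a `cv_grid` supplying periodicity.
#' @param upto_time include hills deposited up to this time.
#' @return numeric bias value(s).
#' @export
bias_value <- function(log, s, grid, upto_time = Inf) {
  hills_value_at(log, s, grid, upto_time)
}

# bias value at arbitrary points from hills with time <= upto_time
hills_value_at <- function(log, s, grid, upto_time = Inf) {
  keep <- log$hills$time <= upto_time
  if (!any(keep)) return(rep(0, if (is.matrix(s)) nrow(s) else 1L))
  s <- as_points(s, log$ndim)
  vapply(seq_len(nrow(s)), function(k) {
    dx <- wrap_displacement(matrix(s[k, ], nrow = sum(keep),
                                   ncol = log$ndim, byrow = TRUE),
                            log$hills$center[keep, , drop = FALSE], grid)
    sum(log$hills$height[keep] *
          exp(-rowSums(dx^2 / (2 * log$hills$sigma[keep, , drop = FALSE]^2))))
  }, numeric(1))
}

#' Deposit one hill
#'
#' Appends a hill at the current CV position. Plain metadynamics uses height
#' `w0`; the well-tempered rule scales it by
#' `exp(-V_current(s) / ((gamma - 1) kT))` where `V_current` is the bias
#' accumulated *before* this deposit, evaluated at the deposit point.
#'
#' @param log a `hills_log`.
#' @param s_now deposit position.
#' @param params a `metad_params`.
#' @param grid a `cv_grid` supplying periodicity for the wrapped distance.
#' @param time deposit time (defaults to last time + pace).
#' @return the extended `hills_log`.
#' @export
deposit_hill <- function(log, s_now, params, grid, time = NULL) {
  d <- log$ndim
  if (is.null(time)) {
    pace <- params$pace
    time <- if (n_hills(log)) log$hills$time[n_hills(log)] + pace else pace
  }
  h <- params$w0
  gamma <- params$bias_factor
  if (!is.null(gamma)) {
    kT <- params$kT %||% log$kT
    vcur <- hills_value_at(log, s_now, grid)
    h <- params$w0 * exp(-vcur / ((gamma - 1) * kT))
  }
  hills_log(c(log$hills$time, time),
            rbind(log$hills$center, matrix(s_now, ncol = d)),
            rbind(log$hills$sigma, matrix(rep_len(params$sigma, d),
                                          ncol = d)),
            c(log$hills$height, h), bias_factor = gamma, kT = log$kT,
            pace = log$pace)
}

hills_upto <- function(log, upto_time) {
  keep <- log$hills$time <= upto_time
  list(center = log$hills$center[keep, , drop = FALSE],
       sigma = log$hills$sigma[keep, , drop = FALSE],
       height = log$hills$height[keep])
}

#' Metadynamics bias on a grid
#'
#' Evaluates the accumulated bias `V(s) = sum_j w_j exp(-sum_a
#' wrap(s - c_j)_a^2 / (2 sigma_ja^2))` over hills with `time <= upto_time`
#' at every grid node. Periodic axes use the minimum-image displacement.
#'
#' @param log a `hills_log`.
#' @param grid a `cv_grid`.
#' @param upto_time include hills deposited up to this time (default all).
#' @return a `scalar_field`.
#' @export
bias_on_grid <- function(log, grid, upto_time = Inf) {
  hh <- hills_upto(log, upto_time)
  if (length(hh$height) == 0L)
    return(scalar_field(grid, rep(0, n_nodes(grid))))
  out <- cpp_hills_grid(hh$center, hh$sigma, hh$height, grid$axes[[1]],
                        if (grid$ndim == 2L) grid$axes[[2]] else numeric(0),
                        grid$periodic, grid_period(grid))
  scalar_field(grid, out$V)
}

#' Gradient of the metadynamics bias on a grid
#'
#' Returns the true derivative `+dV/ds` per axis; [window_mean_force()]
#' subtracts it from the kernel force term.
#'
#' @inheritParams bias_on_grid
#' @return a `vector_field`.
#' @export
bias_gradient_on_grid <- function(log, grid, upto_time = Inf) {
  hh <- hills_upto(log, upto_time)
  if (length(hh$height) == 0L)
    return(vector_field(grid, lapply(seq_len(grid$ndim),
                                     function(a) rep(0, n_nodes(grid)))))
  out <- cpp_hills_grid(hh$center, hh$sigma, hh$height, grid$axes[[1]],
                        if (grid$ndim == 2L) grid$axes[[2]] else numeric(0),
                        grid$periodic, grid_period(grid))
  comps <- list(out$G1)
  if (grid$ndim == 2L) comps <- c(comps, list(out$G2))
  vector_field(grid, comps)
}

#' Incremental bias state
#'
#' Running bias value and gradient fields that can be updated hill-by-hill;
#' adding hills one at a time yields fields identical to batch evaluation.
#'
#' @param grid a `cv_grid`.
#' @return a `bias_state` with `V` (`scalar_field`) and `G` (`vector_field`).
#' @export
bias_state_init <- function(grid) {
  structure(list(grid = grid,
                 V = scalar_field(grid, rep(0, n_nodes(grid))),
                 G = vector_field(grid, lapply(seq_len(grid$ndim),
                                               function(a)
                                                 rep(0, n_nodes(grid))))),
            class = "bias_state")
}

#' Add one hill to an incremental bias state
#'
#' @param state a `bias_state`.
#' @param center,sigma,height the hill.
#' @return the updated `bias_state`.
#' @export
bias_state_add <- function(state, center, sigma, height) {
  g <- state$grid
  d <- g$ndim
  out <- cpp_hills_grid(matrix(center, ncol = d),
                        matrix(rep_len(sigma, d), ncol = d), height,
                        g$axes[[1]],
                        if (d == 2L) g$axes[[2]] else numeric(0),
                        g$periodic, grid_period(g))
  state$V$values <- state$V$values + field_shape(g, out$V)
  state$G$components[[1]] <- state$G$components[[1]] + field_shape(g, out$G1)
  if (d == 2L)
    state$G$components[[2]] <- state$G$components[[2]] +
      field_shape(g, out$G2)
  state
}
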