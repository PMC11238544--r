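#' Kernel density estimation parameters
#'
#' The biased probability density of a time window is a sum of Gaussian
#' kernels of bandwidth `h` scaled by `f_c / prod(h)` (`f_c` is the sampling
#' rate of configurations). The scaling keeps densities from windows with
#' different `h` or `f_c` combinable as weights.
#'
#' @param h per-axis kernel bandwidth (> 0).
#' @param fc sampling-rate scale (> 0), default 1 (unit weight per sample).
#' @return a `kde_params` list.
#' @export
kde_params <- function(h, fc = 1) {
  stopifnot(all(h > 0), fc > 0)
  structure(list(h = as.numeric(h), fc = fc), class = "kde_params")
}

# kernel sums below this value are treated as unexplored, never 0/0
.kde_floor <- 1e-300

kde_sums <- function(samples, grid, kde) {
  d <- grid$ndim
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = d)
  h <- rep_len(kde$h, d)
  cpp_kde(samples, grid$axes[[1]],
          if (d == 2L) grid$axes[[2]] else numeric(0), h, grid$periodic,
          grid_period(grid))
}

#' Biased probability density of a window
#'
#' `p_i(s) = sum_k (f_c / prod(h)) exp(-sum_a wrap(s - s_k)_a^2 / (2 h_a^2))`
#' evaluated at every node; nonnegative everywhere. Used as the weight of the
#' window in all mean-force averages (unnormalized, so windows with more
#' samples weigh more).
#'
#' @param samples CV samples of the window (matrix, one row per sample).
#' @param grid a `cv_grid`.
#' @param kde a `kde_params`.
#' @return a `scalar_field`.
#' @export
window_density <- function(samples, grid, kde) {
  h <- rep_len(kde$h, grid$ndim)
  scalar_field(grid, kde$fc / prod(h) * kde_sums(samples, grid, kde)$ksum)
}

#' Kernel force term of a window
#'
#' The contribution `-kT d ln p_i / ds` to the window mean force, computed in
#' closed form from the same Gaussian kernels as [window_density()]:
#' component `a` is `kT * sum_k (wrap(s - s_k)_a / h_a^2) K_k / sum_k K_k`.
#' Nodes where the kernel sum underflows are returned as `NA` (undefined,
#' not zero).
#'
#' @inheritParams window_density
#' @param kT thermal energy.
#' @return a `vector_field`.
#' @export
window_kde_force <- function(samples, grid, kde, kT = 1) {
  s <- kde_sums(samples, grid, kde)
  bad <- s$ksum < .kde_floor
  comps <- list(ifelse(bad, NA_real_, kT * s$num1 / s$ksum))
  if (grid$ndim == 2L)
    comps <- c(comps, list(ifelse(bad, NA_real_, kT * s$num2 / s$ksum)))
  vector_field(grid, comps)
}

#' Mean force of a window
#'
#' Subtracts every active bias gradient (the metadynamics snapshot of the
#' window plus each static bias) from the kernel force term:
#' `f_i = -kT d ln p_i/ds - sum_b dV_b/ds`. Adding a constant to any bias
#' leaves the result unchanged (only gradients enter).
#'
#' @param kde_force a `vector_field` from [window_kde_force()].
#' @param bias_gradients list of `vector_field`s, one per active bias.
#' @return a `vector_field`.
#' @export
window_mean_force <- function(kde_force, bias_gradients = list()) {
  f <- kde_force
  for (bg in bias_gradients) {
    stopifnot_same_grid(f$grid, bg$grid)
    for (a in seq_len(f$grid$ndim))
      f$components[[a]] <- f$components[[a]] - bg$components[[a]]
  }
  f
}

#' Streaming force accumulator
#'
#' Per-node running sums that implement the weighted average of window mean
#' forces and its weighted variance in one pass: `sumW = sum_i p_i`,
#' `sumWF = sum_i p_i f_i`, `sumWF2 = sum_i p_i f_i^2` (componentwise),
#' `sumW2 = sum_i p_i^2`. Accumulators are additive, which is what makes
#' merging asynchronous simulations exact.
#'
#' @param grid a `cv_grid`.
#' @return a `force_accumulator`.
#' @export
force_accumulator <- function(grid) {
  zero <- function() field_shape(grid, rep(0, n_nodes(grid)))
  zl <- lapply(seq_len(grid$ndim), function(a) zero())
  structure(list(grid = grid, sumW = zero(), sumWF = zl, sumWF2 = zl,
                 sumW2 = zero(), hist = zero(), window_count = 0L),
            class = "force_accumulator")
}

#' @export
print.force_accumulator <- function(x, ...) {
  cat(sprintf("force_accumulator: %d windows, %.0f explored nodes\n",
              x$window_count, sum(x$sumW > 0)))
  invisible(x)
}

#' Accumulate one window
#'
#' Adds a window's density (weight) and mean force into the running sums.
#' Nodes where the force is undefined contribute zero weight.
#'
#' @param acc a `force_accumulator`.
#' @param density the window's `scalar_field` density.
#' @param force the window's `vector_field` mean force.
#' @return the updated `force_accumulator`.
#' @export
accumulate <- function(acc, density, force) {
  stopifnot_same_grid(acc$grid, density$grid)
  stopifnot_same_grid(acc$grid, force$grid)
  ok <- is.finite(force$components[[1]])
  for (a in seq_len(acc$grid$ndim))
    ok <- ok & is.finite(force$components[[a]])
  w <- ifelse(ok, density$values, 0)
  acc$sumW <- acc$sumW + w
  acc$sumW2 <- acc$sumW2 + w * w
  for (a in seq_len(acc$grid$ndim)) {
    f <- ifelse(ok, force$components[[a]], 0)
    acc$sumWF[[a]] <- acc$sumWF[[a]] + w * f
    acc$sumWF2[[a]] <- acc$sumWF2[[a]] + w * f * f
  }
  acc$window_count <- acc$window_count + 1L
  acc
}

#' Mean force from an accumulator
#'
#' @param acc a `force_accumulator` (or `sim_force_record`).
#' @return a `vector_field`, `NA` at unexplored nodes (`sumW == 0`).
#' @export
mean_force <- function(acc) {
  if (inherits(acc, "sim_force_record")) acc <- acc$accumulator
  vector_field(acc$grid, lapply(acc$sumWF, function(swf)
    ifelse(acc$sumW > 0, swf / ifelse(acc$sumW > 0, acc$sumW, 1),
           NA_real_)))
}

#' Explored-region mask of an accumulator
#'
#' @inheritParams mean_force
#' @return logical array, `TRUE` where any window contributed weight.
#' @export
explored_mask <- function(acc) {
  if (inherits(acc, "sim_force_record")) acc <- acc$accumulator
  acc$sumW > 0
}

#' Partition a trajectory into constant-bias time windows
#'
#' Window `i` collects the samples recorded while exactly `i` hills were
#' active: a sample at time `t` belongs to window `i` when `i` hills have
#' `time <= t` (half-open convention: a sample at exactly a deposit time is
#' the first of the new window). With no hills the whole trajectory is one
#' window (the umbrella-sampling limit).
#'
#' @param trajectory a `cv_trajectory`.
#' @param hills a `hills_log` (possibly empty).
#' @param window_time for hill-free (static-bias) trajectories: split the
#'   run into pseudo-windows of this duration -- every subdivision of a
#'   static-bias run is still a constant-bias window, and subdividing is
#'   what makes on-the-fly convergence statistics available in the
#'   umbrella-sampling limit. `NULL` (default) keeps one window.
#' @return list with `index` (per-sample window index, 0-based) and
#'   `windows`, a list of per-window sample row indices (only windows with
#'   samples are listed, in time order, with their hill count `nhills`).
#' @export
windows_from_logs <- function(trajectory, hills, window_time = NULL) {
  tt <- trajectory$times
  ht <- hills$hills$time
  if (length(ht) && any(tt < 0))
    stop("timeline diagnostic: samples predate the first window")
  if (length(ht) > 1L && any(diff(ht) <= 0))
    stop("timeline diagnostic: hill times are not strictly increasing")
  idx <- if (length(ht)) findInterval(tt, ht)
         else if (!is.null(window_time)) as.integer(floor(tt / window_time))
         else rep(0L, length(tt))
  pseudo <- length(ht) == 0L && !is.null(window_time)
  present <- sort(unique(idx))
  windows <- lapply(present, function(i)
    list(nhills = if (pseudo) 0L else i, rows = which(idx == i)))
  list(index = idx, windows = windows)
}

#' Analyze one biased simulation by mean force integration
#'
#' The full per-simulation MFI pass: partitions the trajectory into
#' constant-bias windows, estimates each window's biased density and kernel
#' force, subtracts the bias gradients active in that window (the
#' metadynamics bias accumulated so far -- updated incrementally -- plus all
#' static biases), and accumulates the density-weighted running sums. Single
#' pass, no lookahead; optionally records an on-the-fly convergence series.
#'
#' @param trajectory a `cv_trajectory` (or a `sim_output`, in which case its
#'   hills and static biases are used unless overridden).
#' @param hills a `hills_log`.
#' @param static_biases list of `cv_potential` biases.
#' @param grid the analysis `cv_grid`.
#' @param kde a `kde_params`; default bandwidth is half the metadynamics
#'   hill width when hills are present, else a Silverman-style rule from the
#'   sample spread.
#' @param kT thermal energy.
#' @param checkpoints optional increasing vector of window counts after
#'   which (`sigma_bar`, `v`, `omega`) are recorded; requires `vp`.
#' @param vp a `volume_params` for the checkpoint series.
#' @param label simulation label for downstream merging.
#' @param window_time pseudo-window duration for hill-free runs (see
#'   [windows_from_logs()]).
#' @return a `sim_force_record` with the accumulator, cumulative density,
#'   histogram and (when requested) a `series` data frame.
#' @export
mfi_analyze <- function(trajectory, hills = NULL, static_biases = list(),
                        grid, kde = NULL, kT = 1, checkpoints = NULL,
                        vp = NULL, label = "sim", window_time = NULL) {
  if (inherits(trajectory, "sim_output")) {
    sim <- trajectory
    trajectory <- sim$trajectory
    if (is.null(hills)) hills <- sim$hills
    if (!length(static_biases)) static_biases <- sim$static_biases
  }
  if (is.null(hills)) hills <- empty_hills_log(grid$ndim, kT = kT)
  if (is.null(kde)) kde <- default_kde(trajectory, hills)
  d <- grid$ndim
  wl <- windows_from_logs(trajectory, hills, window_time = window_time)
  sg <- static_gradient_field(static_biases, grid)
  state <- bias_state_init(grid)
  acc <- force_accumulator(grid)
  hdone <- 0L
  series <- NULL
  cp <- sort(unique(checkpoints))
  record_cp <- function(acc, nwin) {
    cf <- window_variance(acc)
    gm <- global_metric(cf, scalar_field(grid, acc$hist), vp)
    data.frame(window = nwin, sigma_bar = gm$sigma_bar, v = gm$v,
               omega = gm$omega)
  }
  for (w in wl$windows) {
    if (w$nhills > hdone) { # bring the metadynamics bias up to this window
      for (j in (hdone + 1L):w$nhills)
        state <- bias_state_add(state, hills$hills$center[j, ],
                                hills$hills$sigma[j, ],
                                hills$hills$height[j])
      hdone <- w$nhills
    }
    samp <- trajectory$samples[w$rows, , drop = FALSE]
    dens <- window_density(samp, grid, kde)
    kf <- window_kde_force(samp, grid, kde, kT = kT)
    f <- window_mean_force(kf, list(state$G, sg))
    acc <- accumulate(acc, dens, f)
    acc$hist <- acc$hist + field_shape(grid, cpp_histogram(
      samp, grid$axes[[1]], if (d == 2L) grid$axes[[2]] else numeric(0),
      grid$periodic, grid_period(grid)))
    if (length(cp) && acc$window_count >= cp[1]) {
      series <- rbind(series, record_cp(acc, acc$window_count))
      cp <- cp[cp > acc$window_count]
    }
  }
  structure(list(accumulator = acc,
                 cumulative_density = scalar_field(grid, acc$sumW),
                 histogram = scalar_field(grid, acc$hist), label = label,
                 series = series, kT = kT), class = "sim_force_record")
}

default_kde <- function(trajectory, hills) {
  d <- ncol(trajectory$samples)
  if (n_hills(hills) > 0L) {
    kde_params(h = 0.5 * hills$hills$sigma[1L, ])
  } else {
    n <- nrow(trajectory$samples)
    h <- vapply(seq_len(d), function(a)
      1.06 * stats::sd(trajectory$samples[, a]) * n^(-1 / (4 + d)),
      numeric(1))
    kde_params(h = pmax(h, 1e-8))
  }
}

#' @export
print.sim_force_record <- function(x, ...) {
  cat(sprintf("sim_force_record '%s': %d windows, %.1f%% of nodes explored\n",
              x$label, x$accumulator$window_count,
              100 * mean(explored_mask(x))))
  invisible(x)
}

#' Merge independent simulations
#'
#' Combines the mean forces of `M` independently biased simulations as a
#' weighted average with each simulation's cumulative biased density as the
#' weight. Implemented as the field-wise sum of the per-simulation
#' accumulators, so merging is exact (processing a trajectory whole or in
#' pieces gives identical sums) and associative; the explored region is the
#' union.
#'
#' @param records list of `sim_force_record` on a shared grid.
#' @return a merged `sim_force_record`.
#' @export
combine_simulations <- function(records) {
  stopifnot(length(records) >= 1L)
  out <- records[[1L]]
  acc <- out$accumulator
  for (r in records[-1L]) {
    b <- r$accumulator
    stopifnot_same_grid(acc$grid, b$grid)
    acc$sumW <- acc$sumW + b$sumW
    acc$sumW2 <- acc$sumW2 + b$sumW2
    for (a in seq_len(acc$grid$ndim)) {
      acc$sumWF[[a]] <- acc$sumWF[[a]] + b$sumWF[[a]]
      acc$sumWF2[[a]] <- acc$sumWF2[[a]] + b$sumWF2[[a]]
    }
    acc$hist <- acc$hist + b$hist
    acc$window_count <- acc$window_count + b$window_count
  }
  out$accumulator <- acc
  out$cumulative_density <- scalar_field(acc$grid, acc$sumW)
  out$histogram <- scalar_field(acc$grid, acc$hist)
  out$label <- paste(vapply(records, `[[`, character(1), "label"),
                     collapse = "+")
  out$series <- NULL
  out
}
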