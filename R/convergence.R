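#' Weighted variance and standard error of the mean force
#'
#' From the streaming sums of a [force_accumulator()]: per node and
#' component, the weighted variance of the window mean forces is
#' `Var = BC * (sumWF2/sumW - (sumWF/sumW)^2)` with the Kish effective
#' sample size `n_eff = sumW^2 / sumW2` and Bessel correction
#' `BC = n_eff / (n_eff - 1)`; `sigma = sqrt(Var)` and the standard error of
#' the weighted mean is `sigma_E = sigma / sqrt(n_eff)`. With equal weights
#' every quantity reduces to its unweighted textbook form. Per-component
#' fields are retained; the scalar per-node `sigma_E` map is the Euclidean
#' norm over components. Nodes with `n_eff <= 1` are undefined (`NA`), not
#' zero.
#'
#' @param acc a `force_accumulator` or `sim_force_record`.
#' @return a `convergence_field` with `sigma` and `sigma_E` (lists of
#'   per-component `scalar_field`s), `n_eff`, and the scalar `sigma_E_norm`.
#' @export
window_variance <- function(acc) {
  if (inherits(acc, "sim_force_record")) acc <- acc$accumulator
  if (acc$window_count < 1L) stop("accumulator holds no windows")
  g <- acc$grid
  neff <- ifelse(acc$sumW2 > 0, acc$sumW^2 / ifelse(acc$sumW2 > 0,
                                                    acc$sumW2, 1), 0)
  ok <- neff > 1
  bc <- ifelse(ok, neff / (neff - 1), NA_real_)
  sig <- list(); sigE <- list()
  norm2 <- 0
  for (a in seq_along(acc$sumWF)) {
    m1 <- acc$sumWF[[a]] / ifelse(acc$sumW > 0, acc$sumW, 1)
    m2 <- acc$sumWF2[[a]] / ifelse(acc$sumW > 0, acc$sumW, 1)
    va <- bc * pmax(m2 - m1^2, 0)
    va[!ok] <- NA_real_
    sa <- sqrt(va)
    se <- sa / sqrt(neff)
    sig[[a]] <- scalar_field(g, sa)
    sigE[[a]] <- scalar_field(g, se)
    norm2 <- norm2 + se^2
  }
  structure(list(grid = g, sigma = sig, sigma_E = sigE,
                 n_eff = scalar_field(g, ifelse(ok, neff, NA_real_)),
                 sigma_E_norm = scalar_field(g, sqrt(norm2)),
                 defined = ok), class = "convergence_field")
}

#' @export
print.convergence_field <- function(x, ...) {
  cat(sprintf("convergence_field: %d component(s), %.1f%% of nodes defined\n",
              length(x$sigma), 100 * mean(x$defined)))
  invisible(x)
}

#' Explored-volume parameters
#'
#' @param histogram_threshold lower bound on the biased histogram for a node
#'   to count as explored; `NULL` (default) uses 1\% of the mean histogram
#'   over nonzero nodes, computed per call.
#' @return a `volume_params` list.
#' @export
volume_params <- function(histogram_threshold = NULL) {
  if (!is.null(histogram_threshold) && histogram_threshold <= 0)
    stop("histogram_threshold must be positive")
  structure(list(histogram_threshold = histogram_threshold),
            class = "volume_params")
}

vp_threshold <- function(H, vp) {
  thr <- vp$histogram_threshold
  if (is.null(thr)) {
    nz <- H[H > 0]
    if (!length(nz)) stop("histogram is empty: no explored volume")
    thr <- 0.01 * mean(nz)
  }
  thr
}

#' Explored fraction of CV space
#'
#' Fraction of grid nodes whose biased histogram exceeds the threshold;
#' the declared relevant domain is the grid itself.
#'
#' @param histogram a `scalar_field` of configuration counts.
#' @param vp a `volume_params`.
#' @return `v` in (0, 1].
#' @export
explored_volume <- function(histogram, vp = volume_params()) {
  H <- histogram$values
  if (any(H < 0)) stop("histogram must be nonnegative")
  thr <- vp_threshold(H, vp)
  v <- mean(H > thr)
  if (v == 0)
    stop("histogram threshold exceeds max(H): explored volume undefined")
  v
}

#' Global convergence metric
#'
#' `sigma_bar` is the mean standard error of the mean force over the sampled
#' CV space (nodes above the histogram threshold); `omega = sigma_bar / v`
#' penalizes confident-looking estimates that have explored little.
#'
#' @param cf a `convergence_field` from [window_variance()].
#' @param histogram a `scalar_field` of configuration counts.
#' @param vp a `volume_params`.
#' @return list with `sigma_bar`, `v`, `omega`.
#' @export
global_metric <- function(cf, histogram, vp = volume_params()) {
  H <- histogram$values
  thr <- vp_threshold(H, vp)
  v <- mean(H > thr)
  if (v == 0) stop("no sampled nodes above the histogram threshold")
  se <- cf$sigma_E_norm$values
  sel <- (H > thr) & is.finite(se)
  if (!any(sel)) stop("no defined sigma_E values over the sampled region")
  sigma_bar <- mean(se[sel])
  list(sigma_bar = sigma_bar, v = v, omega = sigma_bar / v)
}

#' On-the-fly convergence series
#'
#' Streams the windows of one simulation in time order and records
#' (`sigma_bar`, `v`, `omega`) each time a checkpoint is passed; single
#' pass, no lookahead. The final checkpoint equals a from-scratch batch
#' computation on all windows.
#'
#' @inheritParams mfi_analyze
#' @param checkpoint_every record every this-many windows (default 1).
#' @param vp a `volume_params`.
#' @return a `convergence_series` data frame with columns `window`,
#'   `sigma_bar`, `v`, `omega`, plus the final `sim_force_record` as
#'   attribute `"record"`.
#' @export
on_the_fly_series <- function(trajectory, hills = NULL,
                              static_biases = list(), grid, kde = NULL,
                              kT = 1, checkpoint_every = 1L,
                              vp = volume_params(), window_time = NULL) {
  nw <- if (inherits(trajectory, "sim_output"))
    length(windows_from_logs(trajectory$trajectory,
                             hills %||% trajectory$hills,
                             window_time = window_time)$windows)
  else length(windows_from_logs(trajectory,
                                hills %||% empty_hills_log(grid$ndim),
                                window_time = window_time)$windows)
  cps <- if (nw >= checkpoint_every)
    seq(checkpoint_every, nw, by = checkpoint_every) else integer(0)
  cps <- unique(c(cps, nw))
  rec <- mfi_analyze(trajectory, hills = hills,
                     static_biases = static_biases, grid = grid, kde = kde,
                     kT = kT, checkpoints = cps, vp = vp,
                     window_time = window_time)
  ser <- rec$series
  class(ser) <- c("convergence_series", class(ser))
  attr(ser, "record") <- rec
  ser
}

#' Convergence across a campaign of merged simulations
#'
#' Merges simulations one at a time (in the order given) and records the
#' global metric -- and, when a reference potential is supplied, the AAD of
#' the integrated FES over the explored region and AAD/v -- after each
#' merge. This is the campaign-level analogue of [on_the_fly_series()].
#'
#' @param records list of `sim_force_record`.
#' @param vp a `volume_params`.
#' @param reference optional reference `scalar_field` (gauge-free AAD).
#' @param integrator `"fft"` or `"fd"` for 2D grids.
#' @return a `convergence_series` data frame with one row per merge step.
#' @export
campaign_series <- function(records, vp = volume_params(),
                            reference = NULL,
                            integrator = c("fft", "fd")) {
  integrator <- match.arg(integrator)
  out <- NULL
  run <- NULL
  for (k in seq_along(records)) {
    run <- if (is.null(run)) records[[k]]
           else combine_simulations(list(run, records[[k]]))
    cf <- window_variance(run)
    gm <- global_metric(cf, run$histogram, vp)
    row <- data.frame(checkpoint = k, windows = run$accumulator$window_count,
                      sigma_bar = gm$sigma_bar, v = gm$v, omega = gm$omega)
    if (!is.null(reference)) {
      fr <- integrate_record(run, method = integrator, vp = vp)
      row$aad <- aad(fr, reference)
      row$aad_over_v <- row$aad / gm$v
    }
    out <- rbind(out, row)
  }
  class(out) <- c("convergence_series", class(out))
  out
}

#' Integrate the merged mean force of a record
#'
#' The integration region defaults to the sampled CV space -- nodes whose
#' biased histogram exceeds the [volume_params()] threshold -- rather than
#' every node with nonzero kernel weight: far tails reached only by the
#' wings of a few kernels carry meaningless forces and would contaminate a
#' least-squares solve.
#'
#' @param record a `sim_force_record` (or merged record).
#' @param method `"fft"` or `"fd"` (2D; 1D always uses the trapezoid).
#' @param vp a `volume_params` defining the sampled region.
#' @param mask explicit logical mask overriding `vp`.
#' @return an `fes_result`.
#' @export
integrate_record <- function(record, method = c("fft", "fd"),
                             vp = volume_params(), mask = NULL) {
  method <- match.arg(method)
  f <- mean_force(record)
  if (is.null(mask)) {
    H <- record$accumulator$hist
    mask <- H > vp_threshold(H, vp)
  }
  mask <- mask & explored_mask(record)
  if (record$accumulator$grid$ndim == 1L) integrate_1d(f, mask = mask)
  else if (method == "fft") integrate_2d_fft(f, mask = mask)
  else integrate_2d_fd(f, mask = mask)
}

#' Variance of the mean force across independent simulations
#'
#' Weighted variance of the per-simulation time-averaged mean forces, with
#' each simulation's cumulative biased density as its weight and the Bessel
#' correction taken through the simulation-level effective sample size
#' `n_eff = (sum_j P_j)^2 / sum_j P_j^2`.
#'
#' @param records list of >= 2 `sim_force_record` on a shared grid.
#' @return a `convergence_field`.
#' @export
cross_sim_variance <- function(records) {
  if (length(records) < 2L) stop("need at least two independent simulations")
  g <- records[[1L]]$accumulator$grid
  for (r in records[-1L]) stopifnot_same_grid(g, r$accumulator$grid)
  d <- g$ndim
  sw <- 0; sw2 <- 0
  swf <- vector("list", d); swf2 <- vector("list", d)
  for (a in seq_len(d)) { swf[[a]] <- 0; swf2[[a]] <- 0 }
  for (r in records) {
    P <- r$accumulator$sumW
    mf <- mean_force(r)
    ok <- explored_mask(r)
    w <- ifelse(ok, P, 0)
    sw <- sw + w
    sw2 <- sw2 + w * w
    for (a in seq_len(d)) {
      f <- ifelse(ok, mf$components[[a]], 0)
      swf[[a]] <- swf[[a]] + w * f
      swf2[[a]] <- swf2[[a]] + w * f * f
    }
  }
  pseudo <- structure(list(grid = g, sumW = sw, sumWF = swf, sumWF2 = swf2,
                           sumW2 = sw2, hist = sw,
                           window_count = length(records)),
                      class = "force_accumulator")
  window_variance(pseudo)
}

#' Bootstrap error of the free-energy surface
#'
#' Resamples whole simulations with replacement (windows within a run are
#' correlated; independent runs are not), merges and integrates each
#' replicate, aligns all replicate surfaces by their mean over the common
#' explored region, and reports the per-node standard deviation plus its
#' running global average as a function of bootstrap iteration.
#'
#' @param records list of >= 2 `sim_force_record`.
#' @param n_boot number of bootstrap replicates (>= 10).
#' @param seed RNG seed (fixed seed gives identical output).
#' @param method 2D integrator, `"fft"` or `"fd"`.
#' @param vp a `volume_params`; each record's sampled region is its
#'   histogram above this threshold, and replicates are integrated over the
#'   common sampled region.
#' @return list with `mean_fes` (`scalar_field`), `std_fes`
#'   (`scalar_field`), `mask` (common explored region), and `series`
#'   (data frame: iteration, mean per-node std so far).
#' @export
bootstrap_fes <- function(records, n_boot = 100L, seed = 1L,
                          method = c("fft", "fd"), vp = volume_params()) {
  method <- match.arg(method)
  M <- length(records)
  if (M < 2L) stop("bootstrap needs at least two independent simulations")
  if (n_boot < 10L) stop("n_boot must be at least 10")
  g <- records[[1L]]$accumulator$grid
  set.seed(seed)
  draws <- matrix(sample.int(M, M * n_boot, replace = TRUE), n_boot, M)
  surfaces <- matrix(NA_real_, n_boot, n_nodes(g))
  for (b in seq_len(n_boot)) {
    rep_rec <- combine_simulations(records[draws[b, ]])
    fr <- integrate_record(rep_rec, method = method, vp = vp)
    surfaces[b, ] <- as.vector(fr$fes$values)
  }
  # common explored region: nodes every replicate integrated
  common <- colSums(!is.finite(surfaces)) == 0L
  if (!any(common)) stop("bootstrap replicates share no explored region")
  surfaces <- surfaces - rowMeans(surfaces[, common, drop = FALSE])
  run_mean <- 0; run_m2 <- 0
  series <- data.frame(iteration = integer(0), mean_std = numeric(0))
  for (b in seq_len(n_boot)) {
    v <- surfaces[b, common]
    delta <- v - run_mean
    run_mean <- run_mean + delta / b
    run_m2 <- run_m2 + delta * (v - run_mean)
    if (b >= 2L)
      series <- rbind(series, data.frame(
        iteration = b, mean_std = mean(sqrt(run_m2 / (b - 1)))))
  }
  sd_fin <- mean_fin <- rep(NA_real_, n_nodes(g))
  sd_fin[common] <- sqrt(run_m2 / (n_boot - 1))
  mean_fin[common] <- run_mean
  list(mean_fes = scalar_field(g, mean_fin),
       std_fes = scalar_field(g, sd_fin),
       mask = field_shape(g, as.numeric(common)) > 0.5, series = series)
}

#' Write a convergence series as delimited text
#'
#' @param series a `convergence_series` data frame.
#' @param path output file.
#' @export
write_series <- function(series, path) {
  utils::write.table(as.data.frame(series), path, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(path)
}

#' @export
plot.convergence_series <- function(x, ...) {
  xcol <- if ("checkpoint" %in% names(x)) x$checkpoint else x$window
  graphics::par(mfrow = c(1, 2))
  graphics::plot(xcol, x$sigma_bar, type = "b", xlab = "checkpoint",
                 ylab = "mean sigma_E", ...)
  graphics::plot(xcol, x$omega, type = "b", xlab = "checkpoint",
                 ylab = "omega = sigma_E / v", col = "red3", ...)
  invisible(x)
}

#' @export
plot.fes_result <- function(x, ...) {
  g <- x$fes$grid
  if (g$ndim == 1L)
    graphics::plot(g$axes[[1]], x$fes$values, type = "l", xlab = "s",
                   ylab = "F(s)", ...)
  else
    graphics::image(g$axes[[1]], g$axes[[2]], x$fes$values, xlab = "s1",
                    ylab = "s2", col = grDevices::hcl.colors(64, "viridis"),
                    ...)
  invisible(x)
}
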