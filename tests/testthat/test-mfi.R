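test_that("the window density is a scaled Gaussian kernel sum", {
  g <- make_grid(c(0, 1), 101)
  kde <- kde_params(h = 0.05, fc = 2)
  x0 <- g$axes[[1]][51]
  d <- window_density(matrix(x0), g, kde)
  expect_equal(d$values[51], 2 / 0.05) # f_c / h at the sample
  expect_true(all(d$values >= 0))
  d2 <- window_density(matrix(x0), g, kde_params(h = 0.05, fc = 4))
  expect_equal(d2$values, 2 * d$values)
  # the f_c / h scaling makes the integrated weight bandwidth-independent
  set.seed(3)
  s <- matrix(stats::runif(200, 0.3, 0.7))
  w1 <- sum(window_density(s, g, kde_params(h = 0.02))$values) *
    g$spacing[1]
  w2 <- sum(window_density(s, g, kde_params(h = 0.06))$values) *
    g$spacing[1]
  expect_equal(w1, w2, tolerance = 1e-3)
})

test_that("the kernel force equals -kT dln(p)/ds", {
  g <- make_grid(c(0, 1), 101)
  kde <- kde_params(h = 0.05)
  x0 <- g$axes[[1]][41]
  f <- window_kde_force(matrix(x0), g, kde, kT = 2)
  expect_equal(f$components[[1]], 2 * (g$axes[[1]] - x0) / 0.05^2)
  # symmetric samples: zero force at the midpoint
  fs <- window_kde_force(matrix(c(0.4, 0.6)), g, kde)
  expect_equal(fs$components[[1]][51], 0)
  # finite-difference oracle on log density via shifted grids
  set.seed(8)
  s <- matrix(stats::runif(50, 0.2, 0.8))
  eps <- 1e-6
  gp <- make_grid(c(0 + eps, 1 + eps), 101)
  gm <- make_grid(c(0 - eps, 1 - eps), 101)
  lp <- log(window_density(s, gp, kde)$values)
  lm <- log(window_density(s, gm, kde)$values)
  fd <- -(lp - lm) / (2 * eps)
  f1 <- window_kde_force(s, g, kde, kT = 1)$components[[1]]
  keep <- abs(f1) > 1e-3
  expect_equal(f1[keep], fd[keep], tolerance = 1e-6)
})

test_that("window mean force subtracts every active bias gradient", {
  g <- make_grid(c(-1, 1), 64)
  set.seed(4)
  s <- matrix(stats::rnorm(100, 0, 0.2))
  kf <- window_kde_force(s, g, kde_params(h = 0.05))
  expect_identical(window_mean_force(kf, list())$components, kf$components)
  hb <- gradient_field(harmonic_bias(0.2, 3), g)
  f <- window_mean_force(kf, list(hb))
  expect_equal(f$components[[1]], kf$components[[1]] - hb$components[[1]])
  # a constant bias has zero gradient and changes nothing
  const <- gradient_field(poly1d(7.3), g)
  expect_equal(max(abs(const$components[[1]])), 0)
  expect_identical(window_mean_force(kf, list(hb, const))$components,
                   f$components)
  g2 <- make_grid(c(-1, 1), 32)
  expect_error(window_mean_force(kf, list(gradient_field(poly1d(1), g2))),
               "different grids")
})

test_that("a biased Boltzmann sample recovers the unbiased mean force", {
  # rejection-sample exp(-(U + B)/kT), analyze with B declared; the
  # recovered force must match dU/ds
  U <- us_quartic()
  B <- harmonic_bias(0.3, 2)
  g <- make_grid(c(-1.5, 1.5), 150)
  set.seed(21)
  tot <- function(s) pot_value(U, matrix(s)) + pot_value(B, matrix(s))
  vmax <- exp(-min(vapply(seq(-1.5, 1.5, 0.01), tot, numeric(1))))
  n <- 0; acc <- numeric(0)
  while (n < 1e5) {
    cand <- stats::runif(2e5, -1.5, 1.5)
    keep <- stats::runif(2e5) < exp(-vapply(cand, tot, numeric(1))) / vmax
    acc <- c(acc, cand[keep]); n <- length(acc)
  }
  acc <- acc[1:1e5]
  kf <- window_kde_force(matrix(acc), g, kde_params(h = 0.02))
  f <- window_mean_force(kf, list(gradient_field(B, g)))
  dens <- window_density(matrix(acc), g, kde_params(h = 0.02))
  well <- dens$values > 0.05 * max(dens$values)
  dU <- gradient_field(U, g)$components[[1]]
  aad_f <- mean(abs(f$components[[1]][well] - dU[well]))
  expect_lt(aad_f, 0.05 * max(abs(dU)))
})

test_that("accumulation implements the density-weighted average", {
  acc <- uniform_accumulator(w = c(1, 3), f = c(2, -1))
  mf <- mean_force(acc)
  expect_equal(mf$components[[1]], rep(-0.25, 8)) # (1*2 + 3*(-1)) / 4
  one <- uniform_accumulator(w = 2, f = 5)
  expect_equal(mean_force(one)$components[[1]], rep(5, 8))
  # permutation invariance of the sums
  set.seed(12)
  w <- stats::runif(10); f <- stats::rnorm(10)
  p <- sample(10)
  a1 <- uniform_accumulator(w, f)
  a2 <- uniform_accumulator(w[p], f[p])
  expect_lt(max(abs(a1$sumWF[[1]] - a2$sumWF[[1]])), 1e-12)
  expect_lt(max(abs(mean_force(a1)$components[[1]] -
                    mean_force(a2)$components[[1]])), 1e-12)
})

test_that("merging simulations is exact, associative, and respects regions", {
  g <- make_grid(c(-0.3, 1.3), 100)
  kde <- kde_params(h = 0.02)
  sim <- run_langevin(builtin_potential("multiwell1d"),
                      metad = metad_params(w0 = 0.5, sigma = 0.04,
                                           pace = 100, bias_factor = 10),
                      params = langevin_params(nsteps = 2e4, x0 = 0.1,
                                               seed = 11, dt = 0.002,
                                               sample_stride = 10),
                      domain = c(-0.3, 1.3))
  whole <- mfi_analyze(sim, grid = g, kde = kde)
  expect_identical(combine_simulations(list(whole))$accumulator$sumW,
                   whole$accumulator$sumW) # M = 1 identity
  # split at a window boundary and recombine
  tt <- sim$trajectory$times
  tcut <- sim$hills$hills$time[100]
  mk <- function(sel) cv_trajectory(tt[sel],
                                    sim$trajectory$samples[sel, ,
                                                           drop = FALSE])
  r1 <- mfi_analyze(mk(tt < tcut), hills = sim$hills, grid = g, kde = kde)
  r2 <- mfi_analyze(mk(tt >= tcut), hills = sim$hills, grid = g, kde = kde)
  comb <- combine_simulations(list(r1, r2))
  fw <- mean_force(whole)$components[[1]]
  fc <- mean_force(comb)$components[[1]]
  ok <- is.finite(fw)
  expect_identical(ok, is.finite(fc))
  expect_lt(max(abs(fw[ok] - fc[ok])), 1e-12)
  # associativity
  thirds <- sim$hills$hills$time[c(67, 134)]
  rs <- list(mk(tt < thirds[1]),
             mk(tt >= thirds[1] & tt < thirds[2]),
             mk(tt >= thirds[2]))
  rs <- lapply(rs, mfi_analyze, hills = sim$hills, grid = g, kde = kde)
  ab_c <- combine_simulations(list(combine_simulations(rs[1:2]), rs[[3]]))
  abc <- combine_simulations(rs)
  expect_lt(max(abs(ab_c$accumulator$sumWF[[1]] -
                    abc$accumulator$sumWF[[1]])), 1e-12)
  # disjoint explored regions stay independent
  gg <- make_grid(c(0, 1), 64)
  mkrec <- function(lo, hi, fval) {
    a <- force_accumulator(gg)
    w <- as.numeric(gg$axes[[1]] >= lo & gg$axes[[1]] < hi)
    a <- accumulate(a, scalar_field(gg, w),
                    vector_field(gg, list(rep(fval, 64))))
    structure(list(accumulator = a,
                   cumulative_density = scalar_field(gg, a$sumW),
                   histogram = scalar_field(gg, a$sumW), label = "x"),
              class = "sim_force_record")
  }
  m2 <- combine_simulations(list(mkrec(0, 0.4, 2), mkrec(0.6, 1.01, -1)))
  mfm <- mean_force(m2)$components[[1]]
  expect_equal(mfm[gg$axes[[1]] < 0.4], rep(2, sum(gg$axes[[1]] < 0.4)))
  expect_equal(mfm[gg$axes[[1]] >= 0.6], rep(-1, sum(gg$axes[[1]] >= 0.6)))
})

test_that("windows partition samples with the half-open convention", {
  tr <- cv_trajectory(seq(0, 10, by = 0.5), seq(0, 1, length.out = 21))
  none <- windows_from_logs(tr, empty_hills_log(1))
  expect_length(none$windows, 1L) # static bias: one window
  expect_length(none$windows[[1]]$rows, 21L)
  hl <- hills_log(time = c(2, 4, 6, 8), center = rep(0, 4),
                  sigma = rep(0.1, 4), height = rep(1, 4))
  wl <- windows_from_logs(tr, hl)
  expect_equal(sum(lengths(lapply(wl$windows, `[[`, "rows"))), 21L)
  # a sample at exactly a deposit time opens the new window
  expect_equal(wl$index[tr$times == 2], 1L)
  expect_equal(wl$index[tr$times == 1.5], 0L)
  expect_equal(vapply(wl$windows, `[[`, integer(1), "nhills"), 0:4)
  # pseudo-windows for static-bias runs
  ps <- windows_from_logs(tr, empty_hills_log(1), window_time = 2.5)
  expect_length(ps$windows, 5L)
  expect_true(all(vapply(ps$windows, `[[`, integer(1), "nhills") == 0L))
  # timeline diagnostics
  bad <- cv_trajectory(c(-1, 0, 1), c(0, 0, 0))
  expect_error(windows_from_logs(bad, hl), "predate")
})
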