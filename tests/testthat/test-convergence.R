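test_that("weighted variance matches the brute-force oracle", {
  set.seed(31)
  for (case in 1:20) {
    n <- sample(2:6, 1)
    w <- stats::runif(n, 0.1, 2)
    f <- stats::rnorm(n)
    acc <- uniform_accumulator(w, f)
    cf <- window_variance(acc)
    o <- oracle_weighted_stats(w, f)
    expect_equal(cf$n_eff$values[1], o$n_eff, tolerance = 1e-12)
    expect_equal(cf$sigma[[1]]$values[1], o$sigma, tolerance = 1e-12)
    expect_equal(cf$sigma_E[[1]]$values[1], o$sigma_E, tolerance = 1e-12)
  }
})

test_that("equal weights reduce to the unweighted textbook formulas", {
  set.seed(32)
  f <- stats::rnorm(8)
  acc <- uniform_accumulator(rep(0.7, 8), f)
  cf <- window_variance(acc)
  expect_equal(cf$n_eff$values[1], 8, tolerance = 1e-12)
  expect_equal(cf$sigma[[1]]$values[1], stats::sd(f), tolerance = 1e-12)
  expect_equal(cf$sigma_E[[1]]$values[1], stats::sd(f) / sqrt(8),
               tolerance = 1e-12)
})

test_that("the worked two-window example gives the published numbers", {
  cf <- window_variance(uniform_accumulator(c(1, 3), c(2, -1)))
  # n_eff = 16/10, BC = 1.6/0.6, raw moment 1.75, mean -0.25
  expect_equal(cf$n_eff$values[1], 1.6)
  expect_equal(cf$sigma[[1]]$values[1]^2, (1.6 / 0.6) * (1.75 - 0.0625))
  expect_equal(cf$sigma[[1]]$values[1]^2, 4.5)
  expect_equal(cf$sigma_E[[1]]$values[1], sqrt(4.5) / sqrt(1.6))
})

test_that("degenerate variance cases are flagged, not zeroed", {
  same <- window_variance(uniform_accumulator(c(1, 2, 1), c(3, 3, 3)))
  expect_equal(same$sigma[[1]]$values[1], 0)
  expect_equal(same$sigma_E[[1]]$values[1], 0)
  one <- window_variance(uniform_accumulator(1, 5))
  expect_true(is.na(one$sigma[[1]]$values[1])) # n_eff = 1: undefined
  expect_error(window_variance(force_accumulator(make_grid(c(0, 1), 8))),
               "no windows")
})

test_that("explored volume counts nodes above the histogram threshold", {
  g <- make_grid(c(0, 1), 10)
  full <- scalar_field(g, rep(10, 10))
  expect_equal(explored_volume(full, volume_params(1)), 1)
  half <- scalar_field(g, c(rep(10, 5), rep(0, 5)))
  expect_equal(explored_volume(half, volume_params(1)), 0.5)
  expect_error(explored_volume(half, volume_params(100)), "threshold")
  expect_error(volume_params(-1), "positive")
})

test_that("the global metric divides mean error by explored volume", {
  acc <- uniform_accumulator(c(1, 1, 1), c(0.5, 1.5, 1.0))
  cf <- window_variance(acc)
  gfull <- global_metric(cf, scalar_field(cf$grid, rep(5, 8)),
                         volume_params(1))
  expect_equal(gfull$v, 1)
  expect_equal(gfull$omega, gfull$sigma_bar)
  H2 <- scalar_field(cf$grid, c(rep(5, 4), rep(0, 4)))
  ghalf <- global_metric(cf, H2, volume_params(1))
  expect_equal(ghalf$v, 0.5)
  expect_equal(ghalf$omega, 2 * ghalf$sigma_bar)
})

test_that("discovering a fresh region raises the mean force error", {
  g <- make_grid(c(0, 1), 50)
  x <- g$axes[[1]]
  left <- as.numeric(x < 0.5)
  right <- as.numeric(x >= 0.5)
  acc <- force_accumulator(g)
  set.seed(9)
  # phase one: thirty well-converged windows in the left half
  for (k in 1:30)
    acc <- accumulate(acc, scalar_field(g, left),
                      vector_field(g, list(stats::rnorm(50, 0, 0.05))))
  H1 <- scalar_field(g, 30 * left)
  m1 <- global_metric(window_variance(acc), H1, volume_params(0.5))
  # phase two: three scattered windows discover the right half
  for (k in 1:3)
    acc <- accumulate(acc, scalar_field(g, right),
                      vector_field(g, list(stats::rnorm(50, 0, 2))))
  H2 <- scalar_field(g, 30 * left + 3 * right)
  m2 <- global_metric(window_variance(acc), H2, volume_params(0.5))
  expect_gt(m2$sigma_bar, m1$sigma_bar)
  expect_gt(m2$v, m1$v)
})

test_that("the on-the-fly series is single-pass and ends at the batch value", {
  sim <- fixture("metad1d_small", run_langevin(
    builtin_potential("multiwell1d"),
    metad = metad_params(w0 = 0.5, sigma = 0.04, pace = 100,
                         bias_factor = 10),
    params = langevin_params(nsteps = 2e4, x0 = 0.1, seed = 11,
                             dt = 0.002, sample_stride = 10),
    domain = c(-0.3, 1.3)))
  g <- make_grid(c(-0.3, 1.3), 100)
  ser <- on_the_fly_series(sim, grid = g, kde = kde_params(h = 0.02),
                           checkpoint_every = 50, vp = volume_params())
  expect_true(all(diff(ser$window) > 0))
  rec <- attr(ser, "record")
  batch <- global_metric(window_variance(rec), rec$histogram,
                         volume_params())
  last <- ser[nrow(ser), ]
  expect_equal(last$sigma_bar, batch$sigma_bar, tolerance = 1e-12)
  expect_equal(last$v, batch$v, tolerance = 1e-12)
  expect_equal(last$omega, batch$omega, tolerance = 1e-12)
  # single checkpoint equals the batch directly
  ser1 <- on_the_fly_series(sim, grid = g, kde = kde_params(h = 0.02),
                            checkpoint_every = 1e6, vp = volume_params())
  expect_equal(ser1$omega[nrow(ser1)], batch$omega, tolerance = 1e-12)
})

test_that("omega decreases over a converging restrained run", {
  quartic <- us_quartic()
  g <- make_grid(c(-1.6, 1.6), 100)
  wins <- vapply(1:5, function(s) {
    sim <- run_langevin(quartic,
                        static_biases = list(harmonic_bias(0.5, 5)),
                        params = langevin_params(nsteps = 5e4, x0 = 0.5,
                                                 seed = 60 + s,
                                                 sample_stride = 10),
                        domain = c(-1.6, 1.6))
    ser <- on_the_fly_series(sim, grid = g, kde = kde_params(h = 0.05),
                             checkpoint_every = 5, vp = volume_params(),
                             window_time = 25)
    ser$omega[nrow(ser)] < ser$omega[1]
  }, logical(1))
  expect_gte(sum(wins), 3) # 5-seed majority
})

test_that("cross-simulation variance follows the weighted formulas", {
  g <- make_grid(c(0, 1), 8)
  mkrec <- function(w, f) {
    acc <- accumulate(force_accumulator(g), scalar_field(g, rep(w, 8)),
                      vector_field(g, list(rep(f, 8))))
    structure(list(accumulator = acc,
                   cumulative_density = scalar_field(g, acc$sumW),
                   histogram = scalar_field(g, acc$sumW), label = "r"),
              class = "sim_force_record")
  }
  same <- cross_sim_variance(list(mkrec(1, 2), mkrec(1, 2), mkrec(1, 2)))
  expect_equal(same$sigma_E[[1]]$values[1], 0)
  # M = 2, equal weights: Var = BC ((f1 - f2)/2)^2 structure
  two <- cross_sim_variance(list(mkrec(1, 3), mkrec(1, -1)))
  o <- oracle_weighted_stats(c(1, 1), c(3, -1))
  expect_equal(two$sigma[[1]]$values[1], o$sigma, tolerance = 1e-12)
  expect_equal(o$var, 2 * ((3 - (-1)) / 2)^2)
  # permutation invariance
  a <- cross_sim_variance(list(mkrec(1, 3), mkrec(2, -1), mkrec(0.5, 0)))
  b <- cross_sim_variance(list(mkrec(0.5, 0), mkrec(1, 3), mkrec(2, -1)))
  expect_equal(a$sigma_E[[1]]$values, b$sigma_E[[1]]$values,
               tolerance = 1e-12)
  expect_error(cross_sim_variance(list(mkrec(1, 1))), "at least two")
})

test_that("duplicating the whole window set shrinks the standard error", {
  set.seed(14)
  w <- stats::runif(6, 0.2, 1)
  f <- stats::rnorm(6)
  acc1 <- uniform_accumulator(w, f)
  acc2 <- uniform_accumulator(c(w, w), c(f, f))
  s1 <- window_variance(acc1)$sigma_E[[1]]$values[1]
  s2 <- window_variance(acc2)$sigma_E[[1]]$values[1]
  expect_lt(s2, s1)
})

test_that("bootstrap errors are deterministic and vanish for identical input", {
  g <- make_grid(c(-1.6, 1.6), 100)
  sims <- fixture("us_small", us_campaign(6, 5000, seed_base = 400))
  recs <- us_records(sims, g)
  same <- bootstrap_fes(rep(recs[1], 5), n_boot = 20, seed = 2)
  expect_equal(max(same$std_fes$values[same$mask]), 0)
  b1 <- bootstrap_fes(recs, n_boot = 20, seed = 3)
  b2 <- bootstrap_fes(recs, n_boot = 20, seed = 3)
  expect_identical(b1$std_fes$values, b2$std_fes$values)
  b3 <- bootstrap_fes(recs, n_boot = 20, seed = 4)
  expect_false(identical(b1$std_fes$values, b3$std_fes$values))
  expect_error(bootstrap_fes(recs[1], n_boot = 20), "at least two")
  expect_error(bootstrap_fes(recs, n_boot = 5), "at least 10")
  expect_equal(nrow(b1$series), 19L)
})
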