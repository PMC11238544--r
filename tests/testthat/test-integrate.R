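test_that("1D integration recovers known profiles by trapezoid", {
  g <- make_grid(c(-1.6, 1.6), 1000)
  zero <- integrate_1d(vector_field(g, list(rep(0, 1000))))
  expect_equal(zero$fes$values, rep(0, 1000))
  # force = dU/ds of a known quartic recovers the quartic
  U <- us_quartic()
  r <- integrate_1d(gradient_field(U, g))
  ref <- reference_fes(U, g)
  expect_lt(max(abs(r$fes$values - ref$values)), 1e-4)
  expect_equal(min(r$fes$values), 0)
  # gaps split the domain into independently gauged segments
  f <- gradient_field(U, g)
  f$components[[1]][450:550] <- NA
  rs <- integrate_1d(f)
  expect_equal(rs$segments, 2L)
  expect_true(all(is.na(rs$fes$values[450:550])))
  expect_equal(min(rs$fes$values[1:449]), 0)
})

test_that("Fourier integration solves grad F = g in the least-squares sense", {
  # analytic gradient of the double well over [-3,3]^2
  g200 <- make_grid(list(c(-3, 3), c(-3, 3)), 200)
  dw <- builtin_potential("doublewell2d")
  r <- integrate_2d_fft(gradient_field(dw, g200))
  expect_lt(aad(r, reference_fes(dw, g200)), 0.05)
  # band-limited periodic field: recovery to numerical tolerance
  gp <- make_grid(list(c(0, 2 * pi), c(0, 2 * pi)), 64,
                  periodic = c(TRUE, TRUE))
  x <- gp$axes[[1]]; y <- gp$axes[[2]]
  F <- outer(x, y, function(a, b)
    sin(a) + 0.5 * cos(2 * a + b) + 0.3 * sin(a - 2 * b))
  Gx <- outer(x, y, function(a, b)
    cos(a) - sin(2 * a + b) + 0.3 * cos(a - 2 * b))
  Gy <- outer(x, y, function(a, b)
    -0.5 * sin(2 * a + b) - 0.6 * cos(a - 2 * b))
  rp <- integrate_2d_fft(vector_field(gp, list(Gx, Gy)))
  expect_lt(sqrt(mean(((rp$fes$values - mean(rp$fes$values)) -
                       (F - mean(F)))^2)), 1e-6)
  expect_lt(rp$residual, 1e-10)
  # a pure-curl field cannot be integrated: the residual says so
  curl <- vector_field(gp, list(outer(x, y, function(a, b) cos(b)),
                                outer(x, y, function(a, b) sin(a))))
  rc <- integrate_2d_fft(curl)
  rms_in <- sqrt(mean(curl$components[[1]]^2 + curl$components[[2]]^2))
  expect_equal(rc$residual, rms_in, tolerance = 0.05)
  # all-zero force integrates to a flat surface
  rz <- integrate_2d_fft(vector_field(gp, list(0 * Gx, 0 * Gy)))
  expect_equal(max(abs(rz$fes$values)), 0)
  expect_equal(rz$residual, 0)
})

test_that("finite-difference integration is consistent with its operator", {
  # aperiodic round trip through the package's own discrete gradient
  g <- make_grid(list(c(-1, 1), c(-1, 1)), 32)
  F <- outer(g$axes[[1]], g$axes[[2]], function(a, b) a^4 + b^3 - a * b)
  r <- integrate_2d_fd(fd_gradient(scalar_field(g, F)))
  expect_lt(sqrt(mean(((r$fes$values - mean(r$fes$values)) -
                       (F - mean(F)))^2)), 1e-8)
  # periodic grids use the exact spectral pseudoinverse of the stencil
  gp <- make_grid(list(c(0, 2 * pi), c(0, 2 * pi)), 32,
                  periodic = c(TRUE, TRUE))
  Fp <- outer(gp$axes[[1]], gp$axes[[2]],
              function(a, b) sin(a) + cos(b) + 0.2 * sin(a + b))
  rp <- integrate_2d_fd(fd_gradient(scalar_field(gp, Fp)))
  expect_lt(sqrt(mean(((rp$fes$values - mean(rp$fes$values)) -
                       (Fp - mean(Fp)))^2)), 1e-8)
})

test_that("the two 2D integrators agree on the analytic double well", {
  g200 <- make_grid(list(c(-3, 3), c(-3, 3)), 200)
  dw <- builtin_potential("doublewell2d")
  gf <- gradient_field(dw, g200)
  rfft <- integrate_2d_fft(gf)
  rfd <- integrate_2d_fd(gf)
  expect_lt(aad(rfft$fes, rfd$fes), 0.02)
})

test_that("masked and degenerate inputs are handled by contract", {
  g <- make_grid(list(c(-1, 1), c(-1, 1)), 24)
  F <- outer(g$axes[[1]], g$axes[[2]], function(a, b) a^2 + b^2)
  gf <- fd_gradient(scalar_field(g, F))
  mask <- matrix(FALSE, 24, 24)
  mask[3:10, 3:10] <- TRUE
  mask[15:22, 15:22] <- TRUE # two disconnected blobs
  r <- integrate_2d_fd(gf, mask = mask)
  expect_true(all(is.na(r$fes$values[!mask])))
  expect_true(all(is.finite(r$fes$values[mask])))
  expect_gte(r$segments, 2L)
  expect_equal(min(r$fes$values[mask[]]), 0)
  # each component carries its own gauge
  expect_equal(min(r$fes$values[3:10, 3:10]), 0)
  expect_equal(min(r$fes$values[15:22, 15:22]), 0)
  # a single explored node gets FES zero
  m1 <- matrix(FALSE, 24, 24); m1[5, 5] <- TRUE
  r1 <- integrate_2d_fd(gf, mask = m1)
  expect_equal(r1$fes$values[5, 5], 0)
})

test_that("the AAD is gauge-invariant and matches a brute-force oracle", {
  g <- make_grid(c(0, 1), 8)
  a <- scalar_field(g, c(1, 2, 3, 0, 0, 0, 0, 0))
  b <- scalar_field(g, c(1, 1, 1, 0, 0, 0, 0, 0))
  mask <- c(rep(TRUE, 3), rep(FALSE, 5))
  av <- a$values[mask]; bv <- b$values[mask]
  oracle <- mean(abs((av - mean(av)) - (bv - mean(bv))))
  expect_equal(aad(a, b, mask = mask), oracle)
  expect_equal(oracle, 2 / 3) # |(-1,0,1) - 0| averaged
  expect_equal(aad(a, a, mask = mask), 0)
  shifted <- scalar_field(g, a$values + 5)
  expect_equal(aad(shifted, a, mask = mask), 0)
  expect_error(aad(a, b, mask = rep(FALSE, 8)), "empty mask")
})

test_that("integration choice is immaterial next to sampling error", {
  camp <- campaign_2d(500)
  merged <- camp$merged
  H <- merged$accumulator$hist
  well <- H > 0.05 * mean(H[H > 0]) # where the force is determined
  rfd <- integrate_record(merged, "fd")
  rft <- integrate_record(merged, "fft")
  a_fd <- aad(rfd, camp$reference, mask = well & rfd$explored_mask)
  a_ft <- aad(rft, camp$reference, mask = well & rft$explored_mask)
  expect_lt(abs(a_fd - a_ft), 0.1 * min(a_fd, a_ft))
})
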