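# Brute-force reference implementations and shared fixtures.

# weighted mean / variance / standard error by direct looping, independent
# of the streaming accumulator path
oracle_weighted_stats <- function(w, f) {
  stopifnot(length(w) == length(f))
  sw <- 0; swf <- 0; swf2 <- 0; sw2 <- 0
  for (k in seq_along(w)) {
    sw <- sw + w[k]
    sw2 <- sw2 + w[k]^2
    swf <- swf + w[k] * f[k]
    swf2 <- swf2 + w[k] * f[k]^2
  }
  m <- swf / sw
  neff <- sw^2 / sw2
  bc <- neff / (neff - 1)
  v <- bc * (swf2 / sw - m^2)
  list(mean = m, n_eff = neff, bc = bc, var = v, sigma = sqrt(v),
       sigma_E = sqrt(v) / sqrt(neff))
}

# central-difference gradient oracle for potentials
oracle_num_grad <- function(pot, s, eps = 1e-5) {
  vapply(seq_along(s), function(a) {
    sp <- s; sm <- s
    sp[a] <- sp[a] + eps
    sm[a] <- sm[a] - eps
    (pot_value(pot, sp) - pot_value(pot, sm)) / (2 * eps)
  }, numeric(1))
}

# build a force accumulator whose every node carries the given per-window
# (weight, force) pairs; 1D grid with 8 nodes
uniform_accumulator <- function(w, f) {
  g <- make_grid(c(0, 1), 8)
  acc <- force_accumulator(g)
  for (k in seq_along(w))
    acc <- accumulate(acc,
                      scalar_field(g, rep(w[k], 8)),
                      vector_field(g, list(rep(f[k], 8))))
  acc
}

# memoised heavy fixtures (shared across test files within one run)
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# the quartic double well used for the umbrella-sampling checks
us_quartic <- function() poly1d(c(5, 0, -10, 0, 5))

# a small umbrella-sampling campaign on the quartic: `n_win` harmonic
# windows, `steps` Langevin steps each
us_campaign <- function(n_win, steps, seed_base, kappa = 20) {
  pot <- us_quartic()
  centers <- seq(-1.2 - 0.1 * (n_win > 12), 1.2 + 0.1 * (n_win > 12),
                 length.out = n_win)
  lapply(seq_len(n_win), function(k)
    run_langevin(pot,
                 static_biases = list(harmonic_bias(centers[k], kappa)),
                 params = langevin_params(nsteps = steps, x0 = centers[k],
                                          seed = seed_base + k,
                                          sample_stride = 5),
                 domain = c(-1.6, 1.6)))
}

us_records <- function(sims, grid, h = 0.02) {
  lapply(sims, function(s)
    mfi_analyze(s, grid = grid, kde = kde_params(h = h), kT = 1))
}

# the 2D well-tempered metadynamics campaign: ten short randomly
# initialized runs on the double well, analyzed on a 100x100 grid with the
# checkpoint series after each merged run
campaign_2d <- function(seed_base) {
  fixture(paste0("campaign2d_", seed_base), {
    pot <- builtin_potential("doublewell2d")
    dom <- list(c(-3, 3), c(-3, 3))
    grid <- make_grid(dom, 100)
    ref <- reference_fes(pot, grid)
    md <- metad_params(w0 = 1, sigma = 0.15, pace = 200, bias_factor = 15)
    sims <- lapply(1:10, function(k)
      run_langevin(pot, metad = md,
                   params = langevin_params(nsteps = 2e5, x0 = "random",
                                            seed = seed_base + k,
                                            sample_stride = 20),
                   domain = dom))
    recs <- lapply(sims, function(s)
      mfi_analyze(s, grid = grid, kde = kde_params(h = 0.1), kT = 1))
    series <- campaign_series(recs, reference = ref, integrator = "fd")
    list(records = recs, merged = combine_simulations(recs),
         series = series, reference = ref, grid = grid)
  })
}

# evaluate campaign seed bases until a 3-of-5 majority is decided; returns
# the per-base pass flags and Pearson correlations actually computed
campaign_majority <- function() {
  fixture("campaign_majority", {
    bases <- c(500, 1700, 2900, 4100, 5300)
    pass <- logical(0)
    pearson <- numeric(0)
    for (b in bases) {
      cs <- campaign_2d(b)$series
      n <- nrow(cs)
      pass <- c(pass, cs$aad[n] < 1 && cs$aad[n] < cs$aad[1])
      pearson <- c(pearson, stats::cor(cs$omega, cs$aad_over_v))
      if (sum(pass) >= 3 || sum(!pass) >= 3) break
    }
    list(pass = pass, pearson = pearson)
  })
}
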