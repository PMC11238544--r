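# mfir — mean force integration for free-energy surfaces

Biased molecular-dynamics simulations — umbrella sampling, metadynamics,
well-tempered metadynamics, or any combination of simultaneous biases —
sample a collective-variable (CV) space under a known perturbation. **mfir**
reconstructs the underlying free-energy surface (FES) F(**s**) in 1D or 2D
CV space by *mean force integration* (MFI): instead of reweighting
probabilities, it estimates the mean thermodynamic force −∇F(**s**) window
by window, averages it with density weights, and integrates it numerically.
Because the mean force needs no alignment constants between differently
biased runs, arbitrary independent, asynchronous simulations can be merged
into a single surface, and convergence can be monitored on the fly.

The package is for simulators who post-process PLUMED-style COLVAR/HILLS
output and for method development on Langevin toy models, which the package
generates itself (no MD engine required).

## The method

For a time window *i* of constant bias (between two metadynamics hill
deposits, or a whole static-bias run), the window mean force is

```
⟨dF/ds⟩_i = −kT ∂ ln p_i(s)/∂s − Σ_b ∂V_b(s)/∂s
```

where p_i is a Gaussian kernel density of the window's samples (bandwidth
h, scale f_c/h so that differently smoothed windows remain combinable) and
the sum runs over every bias active in that window (the accumulated
metadynamics potential plus any static restraints or walls). Windows are
combined as a weighted average with weights p_i(s); M independent
simulations are merged the same way with their cumulative densities as
weights, which is implemented as a field-wise sum of streaming accumulators
(Σp, Σp·f, Σp·f², Σp²) — so merging is exact and associative. The averaged
force is integrated by cumulative trapezoid (1D), a mirror-padded Fourier
least-squares solve, or a sparse finite-difference least-squares solve (2D).

Convergence is tracked through the weighted variance of window forces with
the Kish effective sample size n_eff = (Σp)²/Σp², giving a per-node
standard error σ_E(s); its average over the sampled region, σ̄_E, divided
by the explored volume fraction v gives the global on-the-fly metric
Ω = σ̄_E/v. Independent replicas additionally give a cross-simulation
variance and bootstrap FES error bars.

## Worked example

Ten short, randomly initialized well-tempered metadynamics runs on the
built-in 2D double-well potential, merged into one FES:

```r
library(mfir)
pot  <- builtin_potential("doublewell2d")
dom  <- list(c(-3, 3), c(-3, 3))
grid <- make_grid(dom, 100)
md   <- metad_params(w0 = 1, sigma = 0.15, pace = 200, bias_factor = 15)
sims <- lapply(1:10, function(k)
  run_langevin(pot, metad = md, domain = dom,
               params = langevin_params(nsteps = 2e5, x0 = "random",
                                        seed = 1000 + k, sample_stride = 20)))
recs   <- lapply(sims, mfi_analyze, grid = grid, kde = kde_params(h = 0.1))
series <- campaign_series(recs, reference = reference_fes(pot, grid),
                          integrator = "fd")
tail(series[c("checkpoint", "sigma_bar", "v", "omega", "aad")], 3)
#>    checkpoint sigma_bar      v    omega       aad
#> 8           8 0.9911290 0.3967 2.498435 0.7849124
#> 9           9 0.9411424 0.3980 2.364679 0.7976260
#> 10         10 0.9107126 0.4005 2.273939 0.7935070
```

After ten merged runs the surface deviates from the exact polynomial by
0.79 energy units on average over the sampled 40% of the domain (`aad`),
and the on-the-fly metric Ω decreases in step with it — that correlation is
what lets you judge convergence when no exact reference exists. The merged
surface itself comes from

```r
merged <- combine_simulations(recs)
fes    <- integrate_record(merged, method = "fd")
plot(fes)
```

A YAML-driven command line (`inst/scripts/mfi simulate|analyze|bootstrap`,
demo configs under `inst/extdata/configs/`) wraps the same functions.

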