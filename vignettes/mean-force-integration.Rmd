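---
title: "Mean force integration: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean force integration: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfir)
```

## The estimation problem

A biased simulation samples configurations under a Hamiltonian perturbed by
one or more bias potentials defined in a low-dimensional collective-variable
(CV) space **s**. The free-energy surface F(**s**) is related to the biased
probability density p(**s**) by F = −kT ln p − V up to a constant that
depends on the bias but not on **s**. Estimating F directly therefore
requires alignment constants between runs with different biases; estimating
the *mean thermodynamic force* −∇F does not, because the constant
differentiates away. That is the whole leverage of mean force integration:
work with ∇F, average it across windows and simulations, integrate once at
the end.

Time is divided into windows of constant bias. For metadynamics each
inter-deposit interval is one window; a static-bias (umbrella-sampling) run
is a single window, or — since any subdivision of a constant bias is still a
constant bias — can be sliced into pseudo-windows (`window_time`) when
convergence statistics are wanted. Within window *i*,

    <dF/ds>_i = −kT ∂ ln p_i/∂s − Σ_b ∂V_b/∂s,

with p_i a Gaussian kernel density estimate of the window's samples and the
sum over every active bias: the metadynamics potential accumulated *before*
the window's first sample (hills with deposit time ≤ the window start;
a sample recorded exactly at a deposit time belongs to the new window) plus
each declared static bias. Window estimates are combined as a weighted
average with the unnormalized kernel sums p_i as weights, so windows with
more samples weigh more and the estimator reduces to the pooled one when
biases agree. Merging M independent simulations uses the same weighted
average with each simulation's cumulative density as its weight. All of
this is carried by four per-node streaming sums (Σp, Σp·f, Σp·f², Σp²)
that are additive, which makes split-and-merge processing *exact* (the
test suite checks equality to 1e−12) and merging associative.

## Kernel density choices

The kernel prefactor is f_c / Π_a h_a, the product form extending the 1D
scale so that windows analyzed with different bandwidths or sampling rates
remain mutually combinable; `f_c = 1` assigns unit weight per sample. The
default bandwidth is half the metadynamics hill width when hills are
present, else a Silverman rule from the sample spread; both are ordinary
KDE defaults, and the worked analyses in the tests use h comparable to the
grid spacing because kernel smoothing biases the recovered force by a
factor ≈ σ²/(σ² + h²) on curvature scales σ — visibly degrading an
umbrella-sampling reconstruction when h is several grid cells wide. Nodes
where a window's kernel sum underflows (below 1e−300) are *undefined* for
that window and contribute zero weight, never NaN.

## Convergence estimators

The weighted variance of window forces at a node uses the Kish effective
sample size n_eff = (Σp)²/Σp² and Bessel correction n_eff/(n_eff − 1);
σ_E = σ/√n_eff is the standard error of the weighted mean. With equal
weights every formula collapses to the unweighted textbook form (a property
test checks this to 1e−12). Vector forces are reduced to one σ_E per node
by the Euclidean norm over components — the per-component fields are kept
for inspection — because a single error map per node is what one plots and
averages. σ̄_E averages σ_E over the *sampled* region: nodes whose biased
histogram (raw nearest-node counts, not the KDE) exceeds a threshold,
defaulting to 1% of the mean histogram over nonzero nodes; the threshold is
deliberately a knob since it is an arbitrary lower bound. The explored
volume v is the fraction of the declared grid above that threshold, and
Ω = σ̄_E/v penalizes estimates that look converged only because little has
been explored. Ω is a *qualitative* convergence indicator: window forces
are correlated at small sample counts, so σ_E is not a calibrated error
bar; the package's claim — tested — is that Ω tracks the true deviation
from a known reference across checkpoints (Pearson r ≈ 0.9 on the 2D
campaign), not that it equals it.

For M independent simulations the same variance structure applies across
simulations with cumulative densities as weights (cross-simulation
variance), and bootstrap resampling of whole simulations — never of windows
within one run, which are correlated — gives FES error bands. Replicate
surfaces are mean-aligned over the region every replicate explored before
the per-node standard deviation is taken. Three bootstrap standard
deviations are an upper bracket for the realized deviation from a known
reference; a two-sided per-node band is not a meaningful check, because the
realized error at a node is a single half-normal draw (P(|Z| > 1/3) ≈ 0.74,
below any useful two-sided coverage target).

## Numerical integration

1D surfaces come from cumulative trapezoid integration per contiguous
explored segment, each segment independently gauged. In 2D two methods are
provided and cross-checked:

* **Fourier** least squares: F̂ = −i(k·ĝ)/k². Aperiodic axes are
  mirror-extended (even extension of F, matching odd/even extensions of the
  gradient components) to suppress wrap-around; before the transform a
  polynomial trend (total degree 4, fitted curl-consistently to the force
  over the mask and integrated analytically) is removed, which eliminates
  the boundary ringing that the mirror extension otherwise produces when
  forces are large at the domain edge. Partially explored inputs are
  handled by inpainting sweeps that replace the unexplored gradient with
  the current solution's gradient, so unexplored zeros stop biasing the
  solve inside the mask.
* **Finite differences**: a sparse least-squares solve of the discrete
  gradient system restricted to explored nodes, with 4th-order central
  stencils where they fit, 4th-order one-sided stencils at domain
  boundaries, and graceful degradation to 2nd/1st order at ragged mask
  edges. Disconnected explored components are gauged independently and
  counted. On a fully periodic, fully explored grid the same least-squares
  problem is solved exactly in Fourier space through the stencil's symbol
  (the symmetric stencil's parity null modes make the normal equations
  singular there; the spectral pseudoinverse handles them by minimum norm).

Both methods invert their own gradient operator to ~1e−8 and agree on the
analytic 2D test surface to 1e−4 average absolute deviation (AAD) — far
below the sampling error of any simulated campaign, which is the practical
point: the integration scheme does not matter next to sampling noise. The
FES gauge is min = 0 over the explored region; AAD between surfaces is
computed after aligning each field by its mask mean, making it offset-robust.
The default *integration* region is the sampled region (histogram above the
volume threshold) rather than every node with nonzero kernel weight:
far-tail nodes touched only by kernel wings carry meaningless forces and
would contaminate a least-squares solve.

## The Langevin generator

The bundled simulator provides the package's self-contained data source:
single-particle underdamped Langevin dynamics (BAOAB splitting; overdamped
Euler–Maruyama as an option) on analytical potentials, with the CV equal to
the particle position. Defaults are kT = 1 (all energies in kT units),
m = 1, friction 1, dt = 0.005; with friction 0 the scheme reduces to
velocity Verlet, which is how the integrator's second-order energy behavior
is tested. One RNG per run, seeded explicitly, with one normal draw per
axis per step in fixed order, so the stored-sample stride never alters the
path and campaigns are bit-reproducible. Hills are deposited every `pace`
steps at the current position, immediately *before* any sample stored at
that step — making the simulator's timeline exactly consistent with the
analyzer's half-open window convention. The well-tempered height rule uses
the bias accumulated before the deposit, evaluated at the deposit point.
A trajectory leaving the declared domain beyond a margin aborts loudly:
that is a configuration error (missing walls), not data.

Two built-in landscapes drive the tests: a 1D five-well profile on roughly
[−0.2, 1.2] (several basins below s = 0.5 and one metastable well near
s = 0.8; the exact shape is configurable because the tests rely on
simulate-then-recover self-consistency, not on a particular profile) and
the printed 2D double-well quartic polynomial on [−3, 3]², whose minima sit
near (−1.88, 0.78) and (1.78, −0.83) with a saddle ≈ 15 kT above the global
minimum.

**Study conditions.** The 2D campaigns use ten runs of 2·10⁵ steps,
σ_M = 0.15, w0 = 1 kT, pace 200, bias factor γ = 15 (the bias then fills to
(1 − 1/γ) ≈ 93% of the ~15 kT saddle, so short runs can cross but single
runs rarely recross — the regime the merging machinery is for), analyzed on
a 100×100 grid with h = 0.1. The umbrella-sampling checks use 12 (or 20)
harmonic windows, κ = 20, on a quartic double well with 5·10⁴ (3·10⁴) steps
per window on a 200-node grid with h = 0.02. Analytic integration tests use
200×200 grids. These sizes keep the full suite within a few minutes while
leaving clear margins on every tolerance.

## What the toy data do and do not show

The Langevin models share the essential structure of the target
application — metastability, rare barrier crossings, history-dependent
bias, asynchronous heterogeneous campaigns — but they identify
configuration space with CV space. Real CVs are many-to-one projections:
hidden slow degrees of freedom make window samples correlated in ways no
toy here reproduces, which is precisely why σ_E is treated as a convergence
indicator rather than an error bar. Passing tests demonstrate correctness
of the estimators and their implementation, not calibration on atomistic
data. Multivariate (covarying) hill widths, adaptive-width Gaussians,
multiple-walker shared biases and CV spaces beyond 2D are out of scope; the
grid is uniform and dense enough that node-centered fields resolve the
kernel widths.

## Interfaces

PLUMED COLVAR/HILLS text dialects are read and written at full double
precision (17 significant digits), so disk round trips are bit-faithful and
the disk pipeline reproduces the in-memory mean force to 1e−10. Restart
overlaps keep the later block with a loud warning; unsupported dialect
features (multivariate hills) raise errors instead of being misread.
Surfaces and error maps serialize to a self-describing plain-text grid
format. The `cmd_simulate()` / `cmd_analyze()` / `cmd_bootstrap()` functions
and the thin `inst/scripts/mfi` wrapper drive whole campaigns from YAML
configs; three demo configs ship under `inst/extdata/configs/`.
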