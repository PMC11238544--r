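#' Langevin dynamics parameters
#'
#' Parameters of the underdamped (BAOAB-split) or overdamped (Euler--Maruyama)
#' Langevin integrator used to generate biased CV trajectories on analytical
#' potentials. Energies are in kT units by default (`kT = 1`); time, mass and
#' friction are in the matching reduced units.
#'
#' @param kT thermal energy (> 0).
#' @param friction friction coefficient (inverse time, >= 0; 0 gives the
#'   deterministic NVE limit used for integrator checks).
#' @param mass particle mass (> 0).
#' @param dt time step (> 0).
#' @param nsteps number of integration steps (>= 1).
#' @param x0 initial position, or `"random"` to draw uniformly over the
#'   declared domain.
#' @param seed integer RNG seed; a run is bit-reproducible given its seed.
#' @param sample_stride steps between stored CV samples.
#' @param scheme `"baoab"` (underdamped, default) or `"euler"` (overdamped).
#' @return a `langevin_params` list.
#' @export
langevin_params <- function(kT = 1, friction = 1, mass = 1, dt = 0.005,
                            nsteps = 100000L, x0 = "random", seed = 1L,
                            sample_stride = 10L,
                            scheme = c("baoab", "euler")) {
  scheme <- match.arg(scheme)
  stopifnot(kT > 0, friction >= 0, mass > 0, dt > 0, nsteps >= 1,
            sample_stride >= 1)
  structure(list(kT = kT, friction = friction, mass = mass, dt = dt,
                 nsteps = as.integer(nsteps), x0 = x0,
                 seed = as.integer(seed),
                 sample_stride = as.integer(sample_stride), scheme = scheme),
            class = "langevin_params")
}

#' Run one biased Langevin simulation
#'
#' Integrates a single particle on `potential` plus any `static_biases` plus
#' (optionally) an on-the-fly metadynamics bias built from `metad`. The CV is
#' the particle position. Hills are deposited every `metad$pace` steps at the
#' current position, immediately before any sample stored at the same step,
#' so a sample coinciding with a deposit is the first sample of the new
#' window. A trajectory leaving the declared domain by more than `margin`
#' (aperiodic axes) aborts with a diagnostic, signalling missing walls.
#'
#' @param potential a `cv_potential`.
#' @param static_biases list of `cv_potential` biases (may be empty).
#' @param metad a `metad_params` or `NULL` for no metadynamics.
#' @param params a `langevin_params`.
#' @param domain the simulated CV domain: a `cv_grid`, or bounds as accepted
#'   by [make_grid()]. Used for periodicity, random initialization and the
#'   escape check.
#' @param margin escape margin per axis (default a quarter of the domain
#'   width).
#' @return a `sim_output` with `trajectory` (a `cv_trajectory`), `hills`
#'   (a `hills_log`, possibly empty), `static_biases` and a `params_echo`
#'   provenance record.
#' @export
run_langevin <- function(potential, static_biases = list(), metad = NULL,
                         params = langevin_params(), domain,
                         margin = NULL) {
  if (!inherits(domain, "cv_grid"))
    domain <- make_grid(domain, nbins = 8L)
  d <- domain$ndim
  stopifnot(potential$ndim == d)
  if (is.null(margin)) margin <- 0.25 * (domain$upper - domain$lower)
  margin <- rep_len(margin, d)

  x0 <- params$x0
  if (identical(x0, "random")) {
    # deterministic draw from the run seed, independent of R's global RNG
    u <- ((params$seed * 2654435761) %% 2^31) / 2^31
    x0 <- domain$lower + (domain$upper - domain$lower) *
      ((u + (seq_len(d) - 1) * 0.61803398874989) %% 1)
  }
  stopifnot(length(x0) == d)

  mspec <- if (is.null(metad)) NULL else {
    m <- unclass(metad)
    m$sigma <- rep_len(m$sigma, d)
    if (is.null(m$kT)) m$kT <- params$kT
    m
  }
  out <- cpp_langevin(c(list(unclass(potential)),
                        lapply(static_biases, unclass)),
                      mspec, params$kT, params$friction, params$mass,
                      params$dt, params$nsteps, as.numeric(x0),
                      as.numeric(params$seed), params$sample_stride,
                      domain$lower, domain$upper, domain$periodic, margin,
                      params$scheme)
  traj <- cv_trajectory(out$times, out$samples,
                        stride = params$dt * params$sample_stride)
  hills <- if (is.null(metad)) empty_hills_log(d, kT = params$kT) else
    hills_log(time = out$hill_times, center = out$hill_centers,
              sigma = matrix(rep(mspec$sigma, each = length(out$hill_times)),
                             ncol = d),
              height = out$hill_heights, bias_factor = metad$bias_factor,
              kT = params$kT, pace = params$dt * metad$pace)
  structure(list(trajectory = traj, hills = hills,
                 static_biases = static_biases,
                 params_echo = list(params = params, metad = metad,
                                    potential = potential$label,
                                    domain = list(lower = domain$lower,
                                                  upper = domain$upper,
                                                  periodic = domain$periodic),
                                    x0 = x0, margin = margin)),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("sim_output: %d samples, %d hills (seed %d)\n",
              nrow(x$trajectory$samples), nrow(x$hills$hills),
              x$params_echo$params$seed))
  invisible(x)
}

#' Run a campaign of independent simulations
#'
#' Runs a list of per-run configurations (each a list of arguments for
#' [run_langevin()]) as independent simulations. Seeds must be distinct;
#' results are order-independent because each run has its own RNG.
#'
#' @param spec list of per-run configuration lists with elements `potential`,
#'   `static_biases`, `metad`, `params`, `domain` (and optional `margin`).
#' @return list of `sim_output`, one per run.
#' @export
run_campaign <- function(spec) {
  seeds <- vapply(spec, function(cfg) cfg$params$seed, integer(1))
  if (anyDuplicated(seeds))
    stop("duplicate seeds in campaign: runs would not be independent")
  lapply(spec, function(cfg)
    run_langevin(cfg$potential,
                 static_biases = cfg$static_biases %||% list(),
                 metad = cfg$metad, params = cfg$params,
                 domain = cfg$domain, margin = cfg$margin))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
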